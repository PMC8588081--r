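# Multi-colorspace mean features.

full_mask <- function(h, w) matrix(TRUE, h, w)

# single-pixel reference conversion: the same native-scale definitions
# applied to one pixel, used as the oracle for constant regions
reference_12 <- function(rgb) {
  px <- matrix(rgb, 1, 3)
  ycc <- c(0.299 * rgb[1] + 0.587 * rgb[2] + 0.114 * rgb[3],
           128 - 0.168736 * rgb[1] - 0.331264 * rgb[2] + 0.5 * rgb[3],
           128 + 0.5 * rgb[1] - 0.418688 * rgb[2] - 0.081312 * rgb[3])
  lab <- as.numeric(grDevices::convertColor(px / 255, "sRGB", "Lab"))
  hsv <- as.numeric(grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3], maxColorValue = 255))
  c(rgb, ycc, lab, hsv[1] * 360, hsv[2], hsv[3])
}

test_that("reference colors convert to the documented native scales", {
  white <- roi_color_means(constant_image(c(255, 255, 255), 4, 4), full_mask(4, 4))
  expect_equal(unname(white[1:3]), c(255, 255, 255))
  expect_equal(unname(white[4:6]), c(255, 128, 128))
  expect_equal(unname(white[7:9]), c(100, 0, 0), tolerance = 1e-6)
  expect_equal(unname(white[10:12]), c(0, 0, 1))

  black <- roi_color_means(constant_image(c(0, 0, 0), 4, 4), full_mask(4, 4))
  expect_equal(unname(black), c(0, 0, 0, 0, 128, 128, 0, 0, 0, 0, 0, 0),
               tolerance = 1e-9)

  # frozen cross-implementation checks (scikit-image 0.26 rgb2lab/rgb2hsv,
  # full-range BT.601 by hand); Lab matrices differ in the 2nd decimal
  mid <- roi_color_means(constant_image(c(120, 80, 40), 4, 4), full_mask(4, 4))
  expect_equal(unname(mid[4:6]), c(87.4, 101.25056, 151.25248), tolerance = 1e-9)
  expect_equal(unname(mid[7:9]), c(37.6344049, 12.4650886, 29.8933439), tolerance = 0.2)
  expect_equal(unname(mid[10:12]), c(30, 2 / 3, 120 / 255), tolerance = 1e-9)
})

test_that("RGB block is the arithmetic pixel mean", {
  img <- constant_image(c(0, 0, 0), 1, 2)
  img[1, 2, ] <- 255L
  got <- roi_color_means(img, full_mask(1, 2))
  expect_equal(unname(got[1:3]), c(127.5, 127.5, 127.5))
})

test_that("constant ROIs match the single-pixel reference conversion", {
  set.seed(77)
  for (i in 1:100) {
    rgb <- sample(0:255, 3, replace = TRUE)
    got <- roi_color_means(constant_image(rgb, 5, 3), full_mask(5, 3))
    ref <- reference_12(rgb)
    scale <- c(255, 255, 255, 255, 255, 255, 100, 255, 255, 360, 1, 1)
    expect_lt(max(abs(got - ref) / scale), 1e-6)
  }
})

test_that("features are invariant to pixel order within the mask", {
  set.seed(3)
  img <- array(sample(0:255, 6 * 6 * 3, TRUE), dim = c(6, 6, 3))
  perm <- sample(36)
  shuffled <- img
  for (ch in 1:3) shuffled[, , ch] <- matrix(img[, , ch][perm], 6, 6)
  expect_equal(roi_color_means(img, full_mask(6, 6)),
               roi_color_means(shuffled, full_mask(6, 6)))
})

test_that("rgb means scale linearly with a constant factor", {
  base <- c(40, 60, 80)
  f1 <- roi_color_means(constant_image(base, 4, 4), full_mask(4, 4))
  f2 <- roi_color_means(constant_image(base * 2.5, 4, 4), full_mask(4, 4))
  expect_equal(unname(f2[1:3] / f1[1:3]), rep(2.5, 3))
})

test_that("empty masks and bad inputs are rejected", {
  expect_error(roi_color_means(constant_image(c(1, 2, 3)), matrix(FALSE, 12, 12)),
               "empty mask")
  expect_error(roi_color_means(constant_image(c(1, 2, 3)), matrix(TRUE, 3, 3)),
               "matching")
})

test_that("feature vectors assemble with the documented length and name order", {
  s <- setNames(1:12, feature_names("skin"))
  l <- setNames(101:112, paste0("left_", 1:12))
  r <- setNames(201:212, paste0("right_", 1:12))
  fused <- assemble_features(s, l, r, "fusion")
  expect_length(fused, 36)
  expect_equal(names(fused), feature_names("fusion"))
  expect_equal(unname(fused), c(1:12, 101:112, 201:212))
  expect_match(names(fused)[1], "^skin_rgb_1$")
  expect_match(names(fused)[13], "^left_eye_rgb_1$")
  expect_match(names(fused)[25], "^right_eye_rgb_1$")

  expect_equal(unname(assemble_features(skin12 = s, feature_set = "skin")), 1:12)
  eye <- assemble_features(left12 = l, right12 = l, feature_set = "eye")
  expect_length(eye, 24)
  expect_equal(unname(eye[1:12]), unname(eye[13:24]))
  expect_error(assemble_features(skin12 = s, feature_set = "fusion"), "requires")
})

test_that("scene featurization produces labeled cohort tables", {
  scenes <- generate_cohort(6, 0.5, scene_params(noise_sigma = 3), seed = 2)
  df <- cohort_features(scenes, "fusion")
  expect_equal(dim(df), c(6, 38))
  expect_equal(colnames(df)[1:2], c("subject_id", "label"))
  expect_equal(sum(df$label == "jaundiced"), 3)
  # eye sclera blue depression is visible in the calibrated features
  expect_true(mean(df$left_eye_rgb_3[df$label == "jaundiced"]) <
                mean(df$left_eye_rgb_3[df$label == "healthy"]))
})
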