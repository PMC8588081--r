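# Shared fixtures, built in code and cached for the test run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- builder()
  fixture_cache[[key]]
}

# A small noise-free scene with non-trivial gains and TCB.
fixture_scene <- function() {
  cached("scene", function()
    generate_scene(scene_params(tcb = 250, illumination_gains = c(204, 229, 178) / 255,
                                seed = 3)))
}

# A constant-color test image with a white patch card at the bottom.
constant_image <- function(color, height = 12L, width = 12L) {
  img <- array(0L, dim = c(height, width, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(color[ch])
  img
}

# Minimal card geometry covering the given bbox entirely with a white patch.
simple_card <- function(row_min, row_max, col_min, col_max) {
  b <- rect_box <- list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                        col_min = as.integer(col_min), col_max = as.integer(col_max))
  card_geometry(b, list(white = b), list(white = c(255, 255, 255)))
}

white_stats <- function(mean_rgb, n = 4L) {
  structure(list(mean_rgb = mean_rgb, pixel_count = n), class = "white_patch_stats")
}

# Landmarks for ROI unit tests: a valid 68-point set on a blank frame with
# controllable eyebrow row/columns and eye hexagons.
toy_landmarks <- function(brow_row = 200, brow_cols = seq(150, 300, length.out = 10),
                          H = 400L, W = 400L,
                          right_eye = c(col = 160, row = 250, a = 24, b = 12),
                          left_eye = c(col = 260, row = 250, a = 24, b = 12)) {
  pts <- matrix(0, 68, 2)
  pts[1:17, ] <- cbind(round(seq(60, W - 60, length.out = 17)), H - 40)
  pts[18:27, ] <- cbind(round(brow_cols), brow_row)
  pts[28:36, ] <- cbind(round(W / 2), round(seq(brow_row + 40, brow_row + 80, length.out = 9)))
  hex <- function(e) {
    theta <- c(180, 120, 60, 0, -60, -120) * pi / 180
    cbind(e["col"] + round(e["a"] * cos(theta)), e["row"] - round(e["b"] * sin(theta)))
  }
  pts[37:42, ] <- hex(right_eye)
  pts[43:48, ] <- hex(left_eye)
  pts[49:58, ] <- cbind(round(seq(150, 250, length.out = 10)), H - 70)
  pts[59:68, ] <- cbind(round(seq(160, 240, length.out = 10)), H - 60)
  landmark_set(pts, H, W)
}

# Small featurized cohorts reused across evaluation tests.
fixture_separable_features <- function() {
  cached("sep_feats", function() {
    scenes <- generate_cohort(60, 0.4, scene_params(noise_sigma = 10,
                                                    jaundice_blue_drop = 60),
                              seed = 21)
    cohort_features(scenes, "fusion")
  })
}
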