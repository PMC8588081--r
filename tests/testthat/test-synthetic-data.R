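# Synthetic scene and cohort generator.

test_that("TCB labeling is a pure threshold at 204 and rejects bad input", {
  expect_equal(as.character(label_from_tcb(c(204, 203.9, 0, 280, 203.99999))),
               c("jaundiced", "healthy", "healthy", "jaundiced", "healthy"))
  expect_error(label_from_tcb(-1), "non-negative")
  expect_error(label_from_tcb(NA_real_), "finite")
})

test_that("noise-free unit-gain scene paints regions exactly", {
  sc <- generate_scene(scene_params(tcb = 0, seed = 1))
  img <- sc$image
  face <- true_region_mask(sc, "face")
  sclera <- true_region_mask(sc, "left_sclera")
  skin_only <- face & !true_region_mask(sc, "left_sclera") &
    !true_region_mask(sc, "right_sclera")
  for (ch in 1:3) {
    expect_equal(mean(img[, , ch][skin_only]), sc$params$skin_base_color[ch])
    expect_equal(mean(img[, , ch][sclera]), sc$params$sclera_base_color[ch])
  }
})

test_that("diagonal gain renders the white patch at round(gain * 255)", {
  sc <- generate_scene(scene_params(illumination_gains = c(0.8, 0.8, 0.8), seed = 1))
  patch <- sc$params$card_geometry$patch_bboxes$white
  px <- sc$image[patch$row_min:patch$row_max, patch$col_min:patch$col_max, ]
  for (ch in 1:3) expect_true(all(px[, , ch] == 204))
})

test_that("bilirubin depresses the blue channel linearly (tcb/300 x drop)", {
  sc <- generate_scene(scene_params(tcb = 250, jaundice_blue_drop = 60, seed = 1))
  skin_only <- true_region_mask(sc, "face") & !true_region_mask(sc, "left_sclera") &
    !true_region_mask(sc, "right_sclera")
  expect_equal(mean(sc$image[, , 3][skin_only]), sc$params$skin_base_color[3] - 50)
  expect_equal(sc$true_skin_color[3], sc$params$skin_base_color[3] - 50)
  expect_equal(mean(sc$image[, , 1][skin_only]), sc$params$skin_base_color[1])
})

test_that("scene regeneration under the same seed is bit-exact", {
  p <- scene_params(tcb = 150, noise_sigma = 8, illumination_gains = c(0.7, 0.9, 0.8),
                    seed = 99)
  expect_identical(generate_scene(p)$image, generate_scene(p)$image)
  p2 <- p; p2$seed <- 100L
  expect_false(identical(generate_scene(p)$image, generate_scene(p2)$image))
})

test_that("scene parameter validation rejects out-of-range inputs", {
  expect_error(scene_params(illumination_gains = c(1.2, 1, 1)), "gains")
  expect_error(scene_params(noise_sigma = -1), "noise_sigma")
  expect_error(scene_params(tcb = -5), "tcb")
  expect_error(scene_params(image_height = 100), "at least")
})

test_that("a card overlapping a region of interest is a geometry error", {
  H <- 360L; W <- 320L
  # place the card over the forehead area
  b <- list(row_min = 40L, row_max = 120L, col_min = 80L, col_max = 240L)
  geom <- card_geometry(b, list(white = b), list(white = c(255, 255, 255)))
  expect_error(generate_scene(scene_params(card_geometry = geom)),
               "overlaps a region of interest")
})

test_that("cohort class counts follow round(n * fraction) and tcb ranges", {
  scenes <- generate_cohort(68, 24 / 68, scene_params(), seed = 4)
  labels <- vapply(scenes, function(s) as.character(s$label), "")
  tcb <- vapply(scenes, function(s) s$tcb, 0)
  expect_equal(sum(labels == "jaundiced"), 24)
  expect_equal(sum(labels == "healthy"), 44)
  expect_true(all(tcb[labels == "jaundiced"] >= 204 & tcb[labels == "jaundiced"] <= 300))
  expect_true(all(tcb[labels == "healthy"] >= 0 & tcb[labels == "healthy"] <= 203))

  all_h <- generate_cohort(10, 0, scene_params(), seed = 4)
  expect_true(all(vapply(all_h, function(s) s$label == "healthy", TRUE)))
})

test_that("cohort generation is deterministic under the master seed", {
  a <- generate_cohort(12, 0.33, scene_params(noise_sigma = 4), seed = 7)
  b <- generate_cohort(12, 0.33, scene_params(noise_sigma = 4), seed = 7)
  expect_identical(vapply(a, function(s) s$tcb, 0), vapply(b, function(s) s$tcb, 0))
  expect_identical(a[[5]]$image, b[[5]]$image)
})

test_that("tabular cohort realizes the requested effect size", {
  tc <- generate_tabular(200, 36, effect_size = 5, seed = 13)
  proj <- as.numeric(tc$features %*% rep(1 / sqrt(36), 36))
  sep <- (mean(proj[tc$labels == "jaundiced"]) - mean(proj[tc$labels == "healthy"])) /
    stats::sd(proj - ave(proj, tc$labels))
  expect_lt(abs(sep - 5) / 5, 0.2)

  null <- generate_tabular(400, 12, effect_size = 0, seed = 14)
  d <- colMeans(null$features[null$labels == "jaundiced", ]) -
    colMeans(null$features[null$labels == "healthy", ])
  expect_lt(max(abs(d)), 0.5)

  expect_identical(generate_tabular(50, 24, 2, seed = 9)$features,
                   generate_tabular(50, 24, 2, seed = 9)$features)
  expect_error(generate_tabular(50, 10, 1), "12, 24, 36")
})

test_that("occluded scenes are generated but refuse featurization", {
  sc <- generate_scene(scene_params(occluded = TRUE))
  expect_error(scene_features(sc, "skin"), "occluded")
})
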