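# Synthetic face-like scene generator.
#
# The clinical images behind this pipeline (smartphone photographs of a
# neonate's face with a calibration card on the chest) are private; this
# module generates seeded stand-in scenes with the statistical structure the
# analysis assumes: a skin region and two scleral regions whose color shifts
# toward yellow (a blue-channel depression) with a latent transcutaneous
# bilirubin (TCB) level, a calibration card whose white patch has a known
# reference color, a per-image diagonal illumination gain, and optional
# additive pixel noise.

TCB_THRESHOLD <- 204   # umol/L; at or above -> jaundiced
TCB_NORM <- 300        # umol/L mapped to a normalized bilirubin of 1

#' Label a transcutaneous bilirubin value
#'
#' Applies the clinical labeling rule used throughout the package: a TCB
#' level of 204 umol/L or above is labeled `"jaundiced"`, anything below is
#' `"healthy"`.
#'
#' @param tcb Numeric vector of TCB values in umol/L; must be non-negative.
#' @return Factor with levels `healthy`, `jaundiced`.
#' @examples
#' label_from_tcb(c(0, 203.9, 204, 280))
#' @export
label_from_tcb <- function(tcb) {
  if (!is.numeric(tcb) || any(!is.finite(tcb)))
    stop("`tcb` must be finite numeric", call. = FALSE)
  if (any(tcb < 0)) stop("`tcb` must be non-negative", call. = FALSE)
  factor(ifelse(tcb >= TCB_THRESHOLD, "jaundiced", "healthy"),
         levels = CLASS_LEVELS)
}

#' Calibration-card geometry
#'
#' Describes where the calibration card and its color patches sit in the
#' image, and the reference color of each patch. The patch named `"white"`
#' (reference color 255,255,255) drives white balancing.
#'
#' @param card_bbox Rectangle (from the internal `rect_box()` layout) holding
#'   the whole card.
#' @param patch_bboxes Named list of rectangles; must include `"white"` and
#'   every patch must lie inside `card_bbox`.
#' @param patch_reference_colors Named list of RGB triples (0-255), same
#'   names as `patch_bboxes`.
#' @return An object of class `card_geometry`.
#' @export
card_geometry <- function(card_bbox, patch_bboxes, patch_reference_colors) {
  if (is.null(patch_bboxes$white)) stop("a patch named 'white' is required", call. = FALSE)
  if (!identical(sort(names(patch_bboxes)), sort(names(patch_reference_colors))))
    stop("patch bboxes and reference colors must share names", call. = FALSE)
  if (any(patch_reference_colors$white != c(255, 255, 255)))
    stop("the 'white' patch reference color must be (255,255,255)", call. = FALSE)
  for (nm in names(patch_bboxes)) {
    if (!rect_contains(card_bbox, patch_bboxes[[nm]]))
      stop("patch '", nm, "' lies outside the card bbox", call. = FALSE)
  }
  structure(list(card_bbox = card_bbox, patch_bboxes = patch_bboxes,
                 patch_reference_colors = patch_reference_colors),
            class = "card_geometry")
}

#' Default card geometry for a given image size
#'
#' Places a three-patch card (white, gray, tan) low in the frame, mimicking a
#' card resting on the chest below the face.
#'
#' @param image_height,image_width Image dimensions in pixels.
#' @return A [card_geometry()] object.
#' @export
default_card_geometry <- function(image_height = 360, image_width = 320) {
  H <- image_height; W <- image_width
  card <- rect_box(round(0.76 * H), round(0.95 * H), round(0.125 * W), round(0.875 * W))
  pr0 <- card$row_min + 7L; pr1 <- card$row_max - 7L
  w3 <- (card$col_max - card$col_min - 28L) %/% 3L
  c0 <- card$col_min + 7L
  patches <- list(
    white = rect_box(pr0, pr1, c0, c0 + w3 - 8L),
    gray  = rect_box(pr0, pr1, c0 + w3, c0 + 2L * w3 - 8L),
    tan   = rect_box(pr0, pr1, c0 + 2L * w3, c0 + 3L * w3 - 8L)
  )
  card_geometry(card, patches,
                list(white = c(255, 255, 255), gray = c(128, 128, 128),
                     tan = c(180, 140, 110)))
}

#' Scene generation parameters
#'
#' @param image_height,image_width Image size in pixels (minimum 340 x 240 so
#'   that the fixed-offset forehead box fits on the painted face).
#' @param skin_base_color,sclera_base_color RGB triples (0-255) of the skin
#'   and sclera at TCB 0, before illumination.
#' @param jaundice_blue_drop Blue-channel depression, in intensity units, at
#'   a normalized bilirubin of 1 (TCB = 300 umol/L). Jaundice is rendered as
#'   yellowing, i.e. a linear loss of blue with bilirubin.
#' @param illumination_gains Three per-channel multiplicative gains in (0, 1]
#'   applied to the whole frame (card included), emulating illumination
#'   color cast.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise in
#'   intensity units; 0 gives a noise-free scene.
#' @param card_geometry A [card_geometry()]; defaults to
#'   [default_card_geometry()] for the image size.
#' @param tcb Latent transcutaneous bilirubin in umol/L.
#' @param seed Integer seed controlling the noise draw.
#' @param occluded If `TRUE` the face region is covered by a flat occluder
#'   (emulating a hand or pacifier blocking the face); landmark-based
#'   segmentation of such scenes is meaningless and downstream stages treat
#'   them as excluded.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_height = 360, image_width = 320,
                         skin_base_color = c(224, 172, 140),
                         sclera_base_color = c(250, 250, 245),
                         jaundice_blue_drop = 60,
                         illumination_gains = c(1, 1, 1),
                         noise_sigma = 0,
                         card_geometry = default_card_geometry(image_height, image_width),
                         tcb = 0, seed = 1L, occluded = FALSE) {
  if (image_height < 340 || image_width < 240)
    stop("image must be at least 340 x 240 pixels", call. = FALSE)
  stopifnot(length(skin_base_color) == 3, length(sclera_base_color) == 3,
            length(illumination_gains) == 3)
  if (any(illumination_gains <= 0) || any(illumination_gains > 1))
    stop("illumination gains must lie in (0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (jaundice_blue_drop < 0) stop("jaundice_blue_drop must be >= 0", call. = FALSE)
  if (tcb < 0) stop("tcb must be >= 0", call. = FALSE)
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 skin_base_color = as.numeric(skin_base_color),
                 sclera_base_color = as.numeric(sclera_base_color),
                 jaundice_blue_drop = jaundice_blue_drop,
                 illumination_gains = as.numeric(illumination_gains),
                 noise_sigma = noise_sigma,
                 card_geometry = card_geometry,
                 tcb = tcb, seed = as.integer(seed), occluded = isTRUE(occluded)),
            class = "scene_params")
}

# Fixed frontal face layout, scaled to the frame. Landmark indices follow
# the standard 0-based 68-point convention: 0-16 jaw, 17-26 eyebrows,
# 27-35 nose, 36-41 right eye (image left), 42-47 left eye, 48-67 mouth.
face_layout <- function(H, W) {
  face <- rect_box(round(0.08 * H), round(0.70 * H), round(0.19 * W), round(0.81 * W))
  brow_row <- round(0.50 * H)
  brow_cols <- round(seq(0.28 * W, 0.72 * W, length.out = 10))
  eye_row <- round(0.585 * H)
  eye_a <- round(0.07 * W)    # semi-axis along columns
  eye_b <- round(0.035 * W)   # semi-axis along rows
  eyes <- list(
    right = list(center_row = eye_row, center_col = round(0.345 * W),
                 semi_col = eye_a, semi_row = eye_b),
    left  = list(center_row = eye_row, center_col = round(0.655 * W),
                 semi_col = eye_a, semi_row = eye_b)
  )
  list(face = face, brow_row = brow_row, brow_cols = brow_cols, eyes = eyes)
}

# Six eye landmarks on the hexagon circumscribing the painted sclera
# ellipse: corners at 0/180 degrees, lid points at +-60/120, matching the
# detector convention (two corners, two upper-lid, two lower-lid points).
eye_landmark_points <- function(eye) {
  theta <- c(180, 120, 60, 0, -60, -120) * pi / 180
  cbind(col = eye$center_col + round(eye$semi_col * cos(theta)),
        row = eye$center_row - round(eye$semi_row * sin(theta)))
}

scene_landmarks <- function(H, W) {
  lay <- face_layout(H, W)
  pts <- matrix(NA_real_, 68, 2, dimnames = list(NULL, c("col", "row")))
  # jaw 0-16: arc along the lower face
  tj <- seq(0, pi, length.out = 17)
  pts[1:17, ] <- cbind(round(seq(lay$face$col_min, lay$face$col_max, length.out = 17)),
                       round(lay$eyes$right$center_row + 0.16 * H * sin(tj)))
  # eyebrows 17-26
  pts[18:27, ] <- cbind(lay$brow_cols, rep(lay$brow_row, 10))
  # nose 27-35
  pts[28:36, ] <- cbind(round(W / 2), round(seq(0.60 * H, 0.67 * H, length.out = 9)))
  # eyes 36-41 (right) and 42-47 (left)
  pts[37:42, ] <- eye_landmark_points(lay$eyes$right)
  pts[43:48, ] <- eye_landmark_points(lay$eyes$left)
  # mouth 48-67
  pts[49:58, ] <- cbind(round(seq(0.375 * W, 0.625 * W, length.out = 10)), round(0.72 * H))
  pts[59:68, ] <- cbind(round(seq(0.40 * W, 0.60 * W, length.out = 10)), round(0.74 * H))
  landmark_set(pts, image_height = H, image_width = W)
}

# The painted sclera ellipse is slightly smaller than the ellipse through
# the six eye landmarks, so the landmark hull covers the sclera with only a
# thin skin margin at the corners (as the caruncle does in a real eye).
sclera_semi_factor <- 0.96

# Painted sclera = the visible eye opening: the sclera ellipse together
# with the thin sliver out to the lid landmarks at the corners.
scene_sclera_mask <- function(H, W, eye) {
  ellipse_mask(H, W, eye$center_row, eye$center_col,
               eye$semi_row * sclera_semi_factor, eye$semi_col * sclera_semi_factor) |
    convex_hull_mask(eye_landmark_points(eye), H, W)
}

#' Generate one synthetic scene
#'
#' Paints the face and card, applies the bilirubin-driven blue-channel
#' depression to skin and sclerae, multiplies the whole frame by the
#' per-channel illumination gains, adds noise, and quantizes to 8-bit
#' intensities. Quantization uses ordered dithering when `noise_sigma = 0`
#' so that region means survive 8-bit storage essentially unbiased.
#'
#' @param params A [scene_params()] object.
#' @return An object of class `jaundice_scene`: list with `image` (H x W x 3
#'   integer array, 0-255), `landmarks` ([landmark_set()]), `true_skin_color`
#'   and `true_sclera_color` (pre-illumination RGB), `tcb`, `label`, and
#'   `params`.
#' @examples
#' sc <- generate_scene(scene_params(tcb = 250, seed = 7))
#' sc$label
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  H <- params$image_height; W <- params$image_width
  lay <- face_layout(H, W)
  card <- params$card_geometry

  # The card may not overlap a region of interest.
  forehead <- rect_box(lay$brow_row - 140L, lay$brow_row - 21L,
                       min(lay$brow_cols), max(lay$brow_cols))
  eye_boxes <- lapply(lay$eyes, function(e)
    rect_box(e$center_row - e$semi_row, e$center_row + e$semi_row,
             e$center_col - e$semi_col, e$center_col + e$semi_col))
  for (b in c(list(forehead), eye_boxes)) {
    if (rect_overlaps(card$card_bbox, b))
      stop("card geometry overlaps a region of interest", call. = FALSE)
  }
  if (!rect_contains(rect_box(1L, H, 1L, W), card$card_bbox))
    stop("card geometry does not fit inside the image", call. = FALSE)

  tcb_norm <- min(params$tcb / TCB_NORM, 1)
  drop <- tcb_norm * params$jaundice_blue_drop
  true_skin <- clip(params$skin_base_color - c(0, 0, drop), 0, 255)
  true_sclera <- clip(params$sclera_base_color - c(0, 0, drop), 0, 255)

  img <- array(0, dim = c(H, W, 3))
  img <- paint_rect(img, rect_box(1L, H, 1L, W), c(105, 105, 115))  # background
  img <- paint_rect(img, lay$face, true_skin)
  for (side in c("right", "left"))
    img <- paint_mask(img, scene_sclera_mask(H, W, lay$eyes[[side]]), true_sclera)
  img <- paint_rect(img, card$card_bbox, c(40, 40, 40))
  for (nm in names(card$patch_bboxes))
    img <- paint_rect(img, card$patch_bboxes[[nm]], card$patch_reference_colors[[nm]])
  if (params$occluded)
    img <- paint_rect(img, lay$face, c(70, 60, 55))

  for (ch in 1:3) img[, , ch] <- img[, , ch] * params$illumination_gains[ch]

  if (params$noise_sigma > 0) {
    set.seed(params$seed)
    img <- img + array(stats::rnorm(length(img), 0, params$noise_sigma), dim = dim(img))
    img <- round_half_up(img)
  } else {
    img <- dither_quantize(img)
  }
  img <- clip(img, 0, 255)
  storage.mode(img) <- "integer"

  structure(list(image = img, landmarks = scene_landmarks(H, W),
                 true_skin_color = true_skin, true_sclera_color = true_sclera,
                 tcb = params$tcb, label = label_from_tcb(params$tcb)[1],
                 params = params),
            class = "jaundice_scene")
}

#' Ground-truth region mask of a scene
#'
#' Recomputes, from the scene's layout parameters, the exact pixel mask that
#' [generate_scene()] painted for a region. Used to validate landmark-based
#' segmentation against the generator's ground truth.
#'
#' @param scene A `jaundice_scene`.
#' @param region One of `"face"`, `"left_sclera"`, `"right_sclera"`.
#' @return Logical H x W matrix.
#' @export
true_region_mask <- function(scene, region = c("face", "left_sclera", "right_sclera")) {
  region <- match.arg(region)
  H <- scene$params$image_height; W <- scene$params$image_width
  lay <- face_layout(H, W)
  switch(region,
         face = rect_mask(lay$face, H, W),
         left_sclera = scene_sclera_mask(H, W, lay$eyes$left),
         right_sclera = scene_sclera_mask(H, W, lay$eyes$right))
}

#' Generate a cohort of synthetic scenes
#'
#' Draws TCB values from two uniform ranges (healthy: 0-203, jaundiced:
#' 204-300 umol/L), assigns `round(n * jaundiced_fraction)` subjects to the
#' jaundiced class, samples per-image illumination gains, and renders each
#' scene with a seed derived from the master seed.
#'
#' @param n Number of scenes.
#' @param jaundiced_fraction Proportion of jaundiced subjects in `[0, 1]`.
#' @param params Template [scene_params()]; per-scene `tcb`, gains, and seed
#'   are overridden.
#' @param seed Master seed; the same seed reproduces the cohort bit-exactly.
#' @param gain_range Range from which each per-image, per-channel
#'   illumination gain is drawn.
#' @return List of `jaundice_scene` objects with `subject_id` fields
#'   `"s001"`, `"s002"`, ...
#' @export
generate_cohort <- function(n, jaundiced_fraction, params = scene_params(),
                            seed = 1L, gain_range = c(0.6, 1)) {
  stopifnot(n >= 1, jaundiced_fraction >= 0, jaundiced_fraction <= 1)
  n_j <- round(n * jaundiced_fraction)
  set.seed(seed)
  tcb <- c(stats::runif(n - n_j, 0, 203), stats::runif(n_j, 204, 300))
  tcb <- tcb[sample.int(n)]
  gains <- matrix(stats::runif(3L * n, gain_range[1], gain_range[2]), ncol = 3)
  # snap gains to the 8-bit sensor grid so the white patch renders at an
  # exactly representable level and ground-truth recovery is well defined
  gains <- round(gains * 255) / 255
  scene_seeds <- sample.int(2147483646L, n)
  lapply(seq_len(n), function(i) {
    p <- params
    p$tcb <- tcb[i]
    p$illumination_gains <- gains[i, ]
    p$seed <- scene_seeds[i]
    sc <- generate_scene(p)
    sc$subject_id <- sprintf("s%03d", i)
    sc
  })
}

#' Generate a tabular two-class Gaussian cohort
#'
#' A classifier-stage fixture: two spherical Gaussian classes in `d`
#' dimensions whose means are `effect_size` pooled standard deviations apart
#' along the direction `(1, ..., 1)/sqrt(d)`.
#'
#' @param n Number of samples.
#' @param d Feature dimension; one of 12, 24, 36.
#' @param effect_size Class-mean separation in pooled-sd units; >= 0.
#' @param seed Integer seed.
#' @param jaundiced_fraction Proportion of jaundiced samples.
#' @return List with `features` (n x d matrix), `labels` (factor),
#'   `class_means`, `class_covariances`, `seed`.
#' @export
generate_tabular <- function(n, d, effect_size, seed = 1L, jaundiced_fraction = 0.5) {
  if (!d %in% c(12L, 24L, 36L)) stop("d must be one of 12, 24, 36", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  set.seed(seed)
  n_j <- round(n * jaundiced_fraction)
  labels <- as_label_factor(c(rep("healthy", n - n_j), rep("jaundiced", n_j)))
  direction <- rep(1 / sqrt(d), d)
  x <- matrix(stats::rnorm(n * d), n, d)
  x[labels == "jaundiced", ] <- x[labels == "jaundiced", , drop = FALSE] +
    matrix(effect_size * direction, sum(labels == "jaundiced"), d, byrow = TRUE)
  colnames(x) <- sprintf("f%02d", seq_len(d))
  mu_h <- rep(0, d); mu_j <- effect_size * direction
  list(features = x, labels = labels,
       class_means = list(healthy = mu_h, jaundiced = mu_j),
       class_covariances = list(healthy = diag(d), jaundiced = diag(d)),
       seed = as.integer(seed))
}
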