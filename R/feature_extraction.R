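# Mean color features in four color spaces.
#
# Each region of interest contributes 12 features: the per-channel means of
# its pixels in RGB, full-range BT.601 YCbCr, CIELab (D65 / sRGB), and HSV.
# Conversions are computed per pixel on the calibrated image and then
# averaged, in each space's native scale:
#   rgb    0-255 per channel
#   ycbcr  0-255 (luma), 0-255 centered at 128 (chroma)
#   lab    L 0-100, a/b signed
#   hsv    hue in degrees [0, 360), saturation and value in [0, 1]
# Hue is averaged arithmetically, matching the plain channel-mean feature
# definition; for hues straddling the 0/360 wrap (saturated reds) the
# arithmetic mean is a known caveat.

FEATURE_SPACES <- c("rgb", "ycbcr", "lab", "hsv")

# px: n x 3 matrix of RGB values in 0-255.
rgb_to_ycbcr <- function(px) {
  r <- px[, 1]; g <- px[, 2]; b <- px[, 3]
  cbind(0.299 * r + 0.587 * g + 0.114 * b,
        128 - 0.168736 * r - 0.331264 * g + 0.5 * b,
        128 + 0.5 * r - 0.418688 * g - 0.081312 * b)
}

rgb_to_lab <- function(px) {
  grDevices::convertColor(px / 255, from = "sRGB", to = "Lab")
}

rgb_to_hsv_deg <- function(px) {
  hsv <- t(grDevices::rgb2hsv(t(px), maxColorValue = 255))
  hsv[, 1] <- hsv[, 1] * 360
  hsv
}

#' Mean color features of one region
#'
#' Converts the masked pixels of a (calibrated) image to each of the four
#' color spaces and averages each channel, yielding 12 features.
#'
#' @param image H x W x 3 array of intensities in 0-255.
#' @param mask A `region_mask` or logical H x W matrix with at least one
#'   `TRUE` pixel.
#' @return Named numeric vector of length 12, names `rgb_1` ... `hsv_3` in
#'   space order rgb, ycbcr, lab, hsv.
#' @export
roi_color_means <- function(image, mask) {
  check_image(image)
  if (inherits(mask, "region_mask")) mask <- mask$mask
  if (!is.logical(mask) || !identical(dim(mask), dim(image)[1:2]))
    stop("`mask` must be a logical matrix matching the image", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  px <- cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  blocks <- list(rgb = px, ycbcr = rgb_to_ycbcr(px), lab = rgb_to_lab(px),
                 hsv = rgb_to_hsv_deg(px))
  out <- unlist(lapply(blocks, colMeans), use.names = FALSE)
  names(out) <- paste(rep(FEATURE_SPACES, each = 3), 1:3, sep = "_")
  out
}

#' Assemble a feature vector from per-region blocks
#'
#' Concatenates 12-feature blocks into the three experimental feature sets:
#' `skin` (12 forehead features), `eye` (left then right sclera, 24), and
#' `fusion` (skin, left, right; 36). Names are prefixed `skin_`,
#' `left_eye_`, `right_eye_`.
#'
#' @param skin12,left12,right12 Length-12 blocks from [roi_color_means()];
#'   blocks not required by `feature_set` may be `NULL`.
#' @param feature_set `"skin"`, `"eye"`, or `"fusion"`.
#' @return Named numeric vector of length 12, 24, or 36.
#' @export
assemble_features <- function(skin12 = NULL, left12 = NULL, right12 = NULL,
                              feature_set = c("fusion", "skin", "eye")) {
  feature_set <- match.arg(feature_set)
  need <- switch(feature_set,
                 skin = list(skin = skin12),
                 eye = list(left_eye = left12, right_eye = right12),
                 fusion = list(skin = skin12, left_eye = left12, right_eye = right12))
  for (nm in names(need)) {
    if (is.null(need[[nm]]))
      stop("feature set '", feature_set, "' requires the ", nm, " block", call. = FALSE)
    if (length(need[[nm]]) != 12)
      stop("the ", nm, " block must have 12 features", call. = FALSE)
  }
  out <- unlist(need, use.names = FALSE)
  names(out) <- unlist(lapply(names(need), function(nm)
    paste(nm, paste(rep(FEATURE_SPACES, each = 3), 1:3, sep = "_"), sep = "_")))
  out
}

#' Feature names of a feature set
#'
#' @param feature_set `"skin"`, `"eye"`, or `"fusion"`.
#' @return Character vector of the documented feature name order.
#' @export
feature_names <- function(feature_set = c("fusion", "skin", "eye")) {
  feature_set <- match.arg(feature_set)
  rois <- switch(feature_set, skin = "skin", eye = c("left_eye", "right_eye"),
                 fusion = c("skin", "left_eye", "right_eye"))
  unlist(lapply(rois, function(nm)
    paste(nm, paste(rep(FEATURE_SPACES, each = 3), 1:3, sep = "_"), sep = "_")))
}

#' Featurize one scene
#'
#' Runs the single-subject path: white-balance calibration, landmark ROI
#' segmentation, per-region color means, and block assembly.
#'
#' @param scene A `jaundice_scene`.
#' @param feature_set `"skin"`, `"eye"`, or `"fusion"`.
#' @param calibrate Apply calibration-card white balancing first (default).
#' @return Named feature vector (see [assemble_features()]).
#' @export
scene_features <- function(scene, feature_set = c("fusion", "skin", "eye"),
                           calibrate = TRUE) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(scene, "jaundice_scene"))
  if (isTRUE(scene$params$occluded))
    stop("scene is occluded; landmark segmentation is not valid", call. = FALSE)
  img <- if (calibrate) calibrate_image(scene$image, scene$params$card_geometry)
         else scene$image
  skin12 <- left12 <- right12 <- NULL
  if (feature_set %in% c("skin", "fusion"))
    skin12 <- roi_color_means(img, forehead_roi(scene$landmarks))
  if (feature_set %in% c("eye", "fusion")) {
    left12 <- roi_color_means(img, sclera_roi(scene$landmarks, "left"))
    right12 <- roi_color_means(img, sclera_roi(scene$landmarks, "right"))
  }
  assemble_features(skin12, left12, right12, feature_set)
}

#' Featurize a cohort of scenes
#'
#' @param scenes List of `jaundice_scene` objects (see [generate_cohort()]).
#' @param feature_set `"skin"`, `"eye"`, or `"fusion"`.
#' @param calibrate Apply white balancing first (default).
#' @return Data frame with `subject_id`, `label`, and one column per feature.
#' @export
cohort_features <- function(scenes, feature_set = c("fusion", "skin", "eye"),
                            calibrate = TRUE) {
  feature_set <- match.arg(feature_set)
  rows <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    fv <- scene_features(sc, feature_set, calibrate = calibrate)
    id <- if (is.null(sc$subject_id)) sprintf("s%03d", i) else sc$subject_id
    cbind(data.frame(subject_id = id, label = as.character(sc$label),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  out <- do.call(rbind, rows)
  out$label <- as_label_factor(out$label)
  out
}
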