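# Calibration-card white balancing.
#
# A card with a known white patch is in every frame. The observed mean color
# of that patch under the scene illumination defines a per-channel diagonal
# gain 255 / mean that maps the patch back to reference white and removes
# the illumination color cast from the whole image.

#' Measure the white patch of the calibration card
#'
#' Computes the per-channel arithmetic mean of the pixels inside the card's
#' `"white"` patch on the uncalibrated image.
#'
#' @param image H x W x 3 array of intensities in 0-255.
#' @param card_geometry A [card_geometry()] locating the card and patches.
#' @return An object of class `white_patch_stats`: list with `mean_rgb`
#'   (3 reals) and `pixel_count`.
#' @export
measure_white_patch <- function(image, card_geometry) {
  check_image(image)
  stopifnot(inherits(card_geometry, "card_geometry"))
  b <- card_geometry$patch_bboxes$white
  H <- dim(image)[1]; W <- dim(image)[2]
  if (rect_is_empty(b) || b$row_min < 1 || b$col_min < 1 || b$row_max > H || b$col_max > W)
    stop("white patch region is empty or outside the image", call. = FALSE)
  px <- image[b$row_min:b$row_max, b$col_min:b$col_max, , drop = FALSE]
  mean_rgb <- apply(px, 3, mean)
  if (any(mean_rgb == 0))
    stop("degenerate white patch: a channel mean is zero (white balance would divide by zero)",
         call. = FALSE)
  structure(list(mean_rgb = mean_rgb,
                 pixel_count = prod(dim(px)[1:2])),
            class = "white_patch_stats")
}

#' Apply diagonal white balance
#'
#' Rescales each channel by `255 / mean` of the white patch, rounds half-up,
#' and clips to 0-255. After calibration the white patch maps exactly to
#' reference white (255, 255, 255); pixels already saturated at 255 are not
#' recoverable.
#'
#' @param image H x W x 3 array of intensities in 0-255.
#' @param stats A `white_patch_stats` from [measure_white_patch()].
#' @return Integer image array with the same dimensions.
#' @examples
#' img <- array(rep(c(100, 150, 200), each = 4), dim = c(2, 2, 3))
#' st <- structure(list(mean_rgb = c(200, 150, 250), pixel_count = 4),
#'                 class = "white_patch_stats")
#' apply_white_balance(img, st)[1, 1, ]  # 128 255 204
#' @export
apply_white_balance <- function(image, stats) {
  check_image(image)
  stopifnot(inherits(stats, "white_patch_stats"))
  if (any(stats$mean_rgb <= 0)) stop("invalid white patch stats", call. = FALSE)
  out <- image
  for (ch in 1:3) out[, , ch] <- image[, , ch] * (255 / stats$mean_rgb[ch])
  out <- clip(round_half_up(out), 0, 255)
  storage.mode(out) <- "integer"
  out
}

#' Calibrate an image in one step
#'
#' Convenience wrapper: [measure_white_patch()] then [apply_white_balance()].
#'
#' @inheritParams measure_white_patch
#' @return Calibrated integer image.
#' @export
calibrate_image <- function(image, card_geometry) {
  apply_white_balance(image, measure_white_patch(image, card_geometry))
}
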