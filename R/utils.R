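# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

CLASS_LEVELS <- c("healthy", "jaundiced")

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic round-half-up (base round() is banker's rounding). The tiny
# epsilon absorbs float error in ratios like 255/200 * 100 = 127.499...99,
# whose exact value is the half-integer 127.5.
round_half_up <- function(x) floor(x + 0.5 + 1e-9)

# Axis-aligned pixel rectangle, inclusive integer bounds, 1-based.
rect_box <- function(row_min, row_max, col_min, col_max) {
  stopifnot(length(row_min) == 1, length(col_min) == 1)
  list(row_min = as.integer(row_min), row_max = as.integer(row_max),
       col_min = as.integer(col_min), col_max = as.integer(col_max))
}

rect_is_empty <- function(b) b$row_max < b$row_min || b$col_max < b$col_min

rect_clip <- function(b, height, width) {
  rect_box(max(b$row_min, 1L), min(b$row_max, height),
           max(b$col_min, 1L), min(b$col_max, width))
}

rect_contains <- function(outer, inner) {
  inner$row_min >= outer$row_min && inner$row_max <= outer$row_max &&
    inner$col_min >= outer$col_min && inner$col_max <= outer$col_max
}

rect_overlaps <- function(a, b) {
  a$row_min <= b$row_max && b$row_min <= a$row_max &&
    a$col_min <= b$col_max && b$col_min <= a$col_max
}

rect_mask <- function(b, height, width) {
  m <- matrix(FALSE, height, width)
  if (!rect_is_empty(b)) m[b$row_min:b$row_max, b$col_min:b$col_max] <- TRUE
  m
}

# Paint a rectangle of an H x W x 3 array with an RGB triple.
paint_rect <- function(img, b, color) {
  for (ch in 1:3) img[b$row_min:b$row_max, b$col_min:b$col_max, ch] <- color[ch]
  img
}

paint_mask <- function(img, mask, color) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

# Pixel-center mask of an axis-aligned ellipse.
ellipse_mask <- function(height, width, center_row, center_col, semi_row, semi_col) {
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((rows - center_row) / semi_row)^2 + ((cols - center_col) / semi_col)^2 <= 1
}

# 8x8 Bayer ordered-dither threshold matrix, values in (0, 1).
bayer_matrix <- local({
  b <- matrix(0, 1, 1)
  for (i in 1:3) {
    b <- rbind(cbind(4 * b, 4 * b + 2),
               cbind(4 * b + 3, 4 * b + 1))
  }
  (b + 0.5) / 64
})

# Quantize a real-valued array to integers by ordered dithering: large
# uniform regions keep their mean value to well under one intensity unit,
# while exact integers pass through unchanged.
dither_quantize <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  thr <- bayer_matrix[((seq_len(h) - 1L) %% 8L) + 1L, ((seq_len(w) - 1L) %% 8L) + 1L,
                      drop = FALSE]
  out <- img
  for (ch in seq_len(dim(img)[3])) {
    x <- img[, , ch]
    f <- x - floor(x)
    out[, , ch] <- floor(x) + (f > thr)
  }
  out
}

check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("`image` must be an H x W x 3 array", call. = FALSE)
  invisible(image)
}

as_label_factor <- function(labels) {
  factor(as.character(labels), levels = CLASS_LEVELS)
}

# Derive a child seed (< 2^31) from a master seed and a stream index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}
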