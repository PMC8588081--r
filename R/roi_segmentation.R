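# Landmark-driven segmentation of the regions of interest.
#
# A 68-point facial landmark set (standard 0-based indexing: eyebrows 17-26,
# right eye 36-41, left eye 42-47) defines two kinds of regions:
#   * forehead: an axis-aligned box spanning the eyebrow columns, from 140
#     down to 21 pixels above the highest eyebrow point — i.e. a 120-pixel
#     band starting 20 pixels above the brows, clipped to the image;
#   * sclera: the filled convex hull of the six eye landmarks of one eye.

#' Construct a 68-point landmark set
#'
#' @param points 68 x 2 numeric matrix of pixel coordinates, columns
#'   `(col, row)`, 1-based image coordinates. Row `i + 1` of the matrix is
#'   landmark `i` of the standard 0-based 68-point convention.
#' @param image_height,image_width Dimensions of the image the landmarks
#'   refer to; all points must lie inside.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, image_height, image_width) {
  points <- as.matrix(points)
  if (nrow(points) != 68 || ncol(points) != 2)
    stop("exactly 68 (col, row) points are required", call. = FALSE)
  if (any(!is.finite(points))) stop("landmarks must be finite", call. = FALSE)
  if (any(points[, 1] < 1 | points[, 1] > image_width |
            points[, 2] < 1 | points[, 2] > image_height))
    stop("all landmarks must lie inside the image", call. = FALSE)
  colnames(points) <- c("col", "row")
  structure(list(points = points, image_height = as.integer(image_height),
                 image_width = as.integer(image_width)),
            class = "landmark_set")
}

#' Extract landmark points by 0-based index
#'
#' @param landmarks A [landmark_set()].
#' @param idx0 Integer vector of 0-based landmark indices (0-67).
#' @return Matrix of `(col, row)` coordinates.
#' @export
landmark_points <- function(landmarks, idx0) {
  stopifnot(inherits(landmarks, "landmark_set"), all(idx0 >= 0), all(idx0 <= 67))
  landmarks$points[idx0 + 1L, , drop = FALSE]
}

new_region_mask <- function(mask, label) {
  n <- sum(mask)
  if (n == 0) stop("degenerate ROI: '", label, "' mask is empty", call. = FALSE)
  structure(list(mask = mask, region_label = label, pixel_count = n),
            class = "region_mask")
}

#' Forehead region of interest
#'
#' Builds the forehead box from eyebrow landmarks 18-25 (0-based): columns
#' span the eyebrow extent; rows run from `y_min - 140` to `y_min - 21`
#' inclusive, where `y_min` is the smallest (highest) eyebrow row, leaving a
#' 20-pixel guard band above the brows and a 120-pixel-tall region. The box
#' is clipped to the image; a fully clipped box is an error.
#'
#' @param landmarks A [landmark_set()].
#' @return An object of class `region_mask` with label `"forehead"`.
#' @export
forehead_roi <- function(landmarks) {
  pts <- landmark_points(landmarks, 18:25)
  y_min <- min(pts[, "row"])
  box <- rect_box(y_min - 140, y_min - 21, min(pts[, "col"]), max(pts[, "col"]))
  box <- rect_clip(box, landmarks$image_height, landmarks$image_width)
  if (rect_is_empty(box))
    stop("degenerate ROI: forehead box fully clipped at the image edge", call. = FALSE)
  new_region_mask(rect_mask(box, landmarks$image_height, landmarks$image_width),
                  "forehead")
}

# Rasterize the convex hull of a small point set: pixel centers inside (or
# on) every hull edge. Points are (col, row).
convex_hull_mask <- function(pts, height, width) {
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(hull) < 3) return(matrix(FALSE, height, width))
  poly <- pts[hull, , drop = FALSE]
  signed_area2 <- sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                        c(poly[-1, 1], poly[1, 1]) * poly[, 2])
  if (abs(signed_area2) < 1e-9) return(matrix(FALSE, height, width))
  if (signed_area2 < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  cmin <- max(1L, floor(min(poly[, 1]))); cmax <- min(width, ceiling(max(poly[, 1])))
  rmin <- max(1L, floor(min(poly[, 2]))); rmax <- min(height, ceiling(max(poly[, 2])))
  if (cmax < cmin || rmax < rmin) return(matrix(FALSE, height, width))
  cols <- matrix(cmin:cmax, rmax - rmin + 1L, cmax - cmin + 1L, byrow = TRUE)
  rows <- matrix(rmin:rmax, rmax - rmin + 1L, cmax - cmin + 1L)
  inside <- matrix(TRUE, nrow(rows), ncol(rows))
  k <- nrow(poly)
  for (i in seq_len(k)) {
    a <- poly[i, ]; b <- poly[if (i == k) 1L else i + 1L, ]
    cross <- (b[1] - a[1]) * (rows - a[2]) - (b[2] - a[2]) * (cols - a[1])
    inside <- inside & (cross >= 0 | abs(cross) < 1e-9)
  }
  m <- matrix(FALSE, height, width)
  m[rmin:rmax, cmin:cmax] <- inside
  m
}

#' Sclera region of interest
#'
#' Rasterizes the filled convex hull of the six eye landmarks of the
#' requested eye: points 42-47 (0-based) for the subject's left eye, 36-41
#' for the right eye. The hull excludes the eyelid skin a bounding box would
#' include. Collinear or coincident eye points are an error.
#'
#' @param landmarks A [landmark_set()].
#' @param side `"left"` or `"right"` (the subject's side).
#' @return A `region_mask` with label `"left_sclera"` or `"right_sclera"`.
#' @export
sclera_roi <- function(landmarks, side = c("left", "right")) {
  side <- match.arg(side)
  idx0 <- if (side == "left") 42:47 else 36:41
  pts <- landmark_points(landmarks, idx0)
  m <- convex_hull_mask(pts, landmarks$image_height, landmarks$image_width)
  if (!any(m))
    stop("degenerate ROI: ", side, " eye landmarks are collinear or out of frame",
         call. = FALSE)
  new_region_mask(m, paste0(side, "_sclera"))
}

#' Segment all regions of interest
#'
#' @param landmarks A [landmark_set()].
#' @return Named list of `region_mask` objects: `forehead`, `left_sclera`,
#'   `right_sclera`.
#' @export
segment_rois <- function(landmarks) {
  list(forehead = forehead_roi(landmarks),
       left_sclera = sclera_roi(landmarks, "left"),
       right_sclera = sclera_roi(landmarks, "right"))
}
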