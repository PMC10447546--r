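# Pixel-space geometry shared by annotation I/O, detection and segmentation.
#
# Conventions used throughout the package:
#  * pixel coordinates are 0-based (row, col); pixel (i, j) has its centre at
#    the real-plane point (i, j);
#  * bounding boxes store inclusive corner pixels, so a box spans
#    (row_max - row_min + 1) x (col_max - col_min + 1) pixels;
#  * binary masks are logical matrices in storage order [row + 1, col + 1];
#  * images are numeric matrices on the 8-bit gray scale 0..255.

#' Create a bounding box
#'
#' Boxes are axis-aligned pixel rectangles with 0-based inclusive corners:
#' a box from `(0, 0)` to `(9, 9)` covers 100 pixels.
#'
#' @param row_min,col_min,row_max,col_max Corner pixel indices (0-based,
#'   inclusive).
#' @return An object of class `bbox`.
#' @export
#' @examples
#' b <- bbox(10, 20, 30, 60)
#' box_area(b)
bbox <- function(row_min, col_min, row_max, col_max) {
  vals <- c(row_min, col_min, row_max, col_max)
  if (any(!is.finite(vals))) {
    stop_invalid("bounding box corners must be finite")
  }
  if (row_min > row_max || col_min > col_max) {
    stop_invalid("bounding box corners out of order: min corner must not exceed max corner")
  }
  structure(
    list(row_min = row_min, col_min = col_min,
         row_max = row_max, col_max = col_max),
    class = "bbox"
  )
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox rows [%g, %g] cols [%g, %g]>\n",
              x$row_min, x$row_max, x$col_min, x$col_max))
  invisible(x)
}

#' Coerce a one-row data frame (or list) with corner columns to a `bbox`
#' @param x A list or one-row data frame with `row_min`, `col_min`,
#'   `row_max`, `col_max`.
#' @return A `bbox`.
#' @export
as_bbox <- function(x) {
  if (inherits(x, "bbox")) return(x)
  bbox(x$row_min, x$col_min, x$row_max, x$col_max)
}

#' Bounding box pixel area
#' @param box A [bbox()].
#' @return Number of pixels covered (inclusive-corner convention).
#' @export
box_area <- function(box) {
  box <- as_bbox(box)
  (box$row_max - box$row_min + 1) * (box$col_max - box$col_min + 1)
}

#' Intersection-over-union of two bounding boxes
#'
#' Areas follow the inclusive-pixel convention, so two identical boxes give
#' exactly 1 and disjoint boxes give 0.
#'
#' @param a,b [bbox()] objects (or coercible via [as_bbox()]).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  ir0 <- max(a$row_min, b$row_min); ir1 <- min(a$row_max, b$row_max)
  ic0 <- max(a$col_min, b$col_min); ic1 <- min(a$col_max, b$col_max)
  if (ir0 > ir1 || ic0 > ic1) return(0)
  inter <- (ir1 - ir0 + 1) * (ic1 - ic0 + 1)
  inter / (box_area(a) + box_area(b) - inter)
}

#' Euclidean distance between two pixel points
#'
#' @param a,b Numeric length-2 vectors `(row, col)` (real-valued pixel
#'   coordinates are allowed; annotation points need not sit on the grid).
#' @return Distance in pixels.
#' @export
#' @examples
#' pixel_distance(c(0, 0), c(3, 4)) # 5
pixel_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 2 || length(b) != 2 || any(!is.finite(c(a, b)))) {
    stop_invalid("pixel_distance() expects two finite (row, col) points")
  }
  sqrt(sum((a - b)^2))
}

#' Intersect two binary masks
#'
#' The two-annotator ground-truth rule: the agreed mask is the pixel-wise
#' intersection of the individual annotations.
#'
#' @param a,b Logical matrices of identical shape.
#' @return Logical matrix; member iff member of both inputs.
#' @export
intersect_masks <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b)) {
    stop_validation("masks must be matrices")
  }
  if (!identical(dim(a), dim(b))) {
    stop_validation(sprintf("mask shapes differ: %s vs %s",
                            paste(dim(a), collapse = "x"),
                            paste(dim(b), collapse = "x")))
  }
  (a & b)
}

#' Widest horizontal run of a mask, per row
#'
#' Internal helper: for each row the span rightmost - leftmost + 1 of member
#' pixels (0 for empty rows).
#' @noRd
row_spans <- function(mask) {
  apply(mask, 1, function(r) {
    w <- which(r)
    if (length(w) == 0) 0L else (w[length(w)] - w[1] + 1L)
  })
}

#' Bounding box of the TRUE pixels of a mask
#' @param mask Logical matrix.
#' @return A [bbox()] in 0-based coordinates, or an error if empty.
#' @export
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_validation("mask is empty")
  bbox(min(idx[, 1]) - 1, min(idx[, 2]) - 1,
       max(idx[, 1]) - 1, max(idx[, 2]) - 1)
}

#' Crop a region of interest with an invertible coordinate transform
#'
#' Expands `box` by `margin` pixels on every side, clips to the image, and
#' returns the cropped raster together with the [frame_transform()] mapping
#' full-image coordinates to ROI coordinates.
#'
#' @param image Numeric matrix (gray image) or logical matrix (mask).
#' @param box A [bbox()] in the image frame.
#' @param margin Margin in pixels added on each side before clipping.
#' @return A list with `image` (the crop), `transform` (original -> ROI),
#'   and `box` (the clipped crop extent as a `bbox`).
#' @export
crop_roi <- function(image, box, margin = 0) {
  if (!is.matrix(image)) stop_validation("image must be a matrix")
  box <- as_bbox(box)
  r0 <- floor(box$row_min - margin); r1 <- ceiling(box$row_max + margin)
  c0 <- floor(box$col_min - margin); c1 <- ceiling(box$col_max + margin)
  r0 <- max(r0, 0); c0 <- max(c0, 0)
  r1 <- min(r1, nrow(image) - 1); c1 <- min(c1, ncol(image) - 1)
  if (r0 > r1 || c0 > c1) {
    stop_validation("box (after margin and clipping) lies outside the image")
  }
  roi <- image[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1), drop = FALSE]
  list(
    image = roi,
    transform = frame_transform(row_scale = 1, col_scale = 1,
                                row_offset = r0, col_offset = c0),
    box = bbox(r0, c0, r1, c1)
  )
}
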