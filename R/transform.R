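# Invertible affine frame transforms. Cropping and resizing both change the
# pixel frame; measurements taken in the model frame (e.g. an iris diameter
# on a 256 x 256 ROI) must be mapped back to original-image pixels before
# they can share units with landmark distances annotated on the original.

#' Create a frame transform
#'
#' Maps a point in the original frame to the target frame as
#' `frame = (orig - offset) * scale`, separately per axis. Offsets may be
#' fractional: a bilinear resize aligns pixel *centres*, which introduces a
#' half-pixel offset when the scale differs from 1.
#'
#' @param row_scale,col_scale Positive scale factors (target px per source px).
#' @param row_offset,col_offset Source-frame offsets in pixels.
#' @return An object of class `frame_transform`.
#' @export
frame_transform <- function(row_scale = 1, col_scale = 1,
                            row_offset = 0, col_offset = 0) {
  if (!is.finite(row_scale) || !is.finite(col_scale) ||
      row_scale <= 0 || col_scale <= 0) {
    stop_invalid("frame transform scales must be positive and finite")
  }
  structure(
    list(row_scale = row_scale, col_scale = col_scale,
         row_offset = row_offset, col_offset = col_offset),
    class = "frame_transform"
  )
}

#' @export
print.frame_transform <- function(x, ...) {
  cat(sprintf("<frame_transform scale (%.4g, %.4g) offset (%.4g, %.4g)>\n",
              x$row_scale, x$col_scale, x$row_offset, x$col_offset))
  invisible(x)
}

#' Apply a frame transform to points
#'
#' @param points Numeric matrix (n x 2) of `(row, col)` points, or a length-2
#'   vector for a single point.
#' @param transform A [frame_transform()].
#' @param inverse If `TRUE`, map from the target frame back to the original.
#' @return Points in the mapped frame, same shape as the input.
#' @export
transform_points <- function(points, transform, inverse = FALSE) {
  stopifnot(inherits(transform, "frame_transform"))
  single <- is.null(dim(points))
  pts <- if (single) matrix(as.numeric(points), nrow = 1) else as.matrix(points)
  if (ncol(pts) != 2) stop_invalid("points must be (row, col) pairs")
  out <- pts
  if (!inverse) {
    out[, 1] <- (pts[, 1] - transform$row_offset) * transform$row_scale
    out[, 2] <- (pts[, 2] - transform$col_offset) * transform$col_scale
  } else {
    out[, 1] <- pts[, 1] / transform$row_scale + transform$row_offset
    out[, 2] <- pts[, 2] / transform$col_scale + transform$col_offset
  }
  if (single) drop(out) else out
}

#' Compose two frame transforms
#'
#' `compose_transforms(ab, bc)` returns the transform from frame A straight
#' to frame C when `ab` maps A to B and `bc` maps B to C.
#'
#' @param ab,bc [frame_transform()] objects.
#' @return A single equivalent [frame_transform()].
#' @export
compose_transforms <- function(ab, bc) {
  # (x - o1) s1 -> then (y - o2) s2  ==  (x - (o1 + o2/s1)) s1 s2
  frame_transform(
    row_scale = ab$row_scale * bc$row_scale,
    col_scale = ab$col_scale * bc$col_scale,
    row_offset = ab$row_offset + bc$row_offset / ab$row_scale,
    col_offset = ab$col_offset + bc$col_offset / ab$col_scale
  )
}

#' Map a length measured in a derived frame back to original pixels
#'
#' Lengths are scale-only (offsets cancel), but the two axes may carry
#' different scales after an anisotropic resize, so the measurement axis
#' must be named.
#'
#' @param length_px Length measured in the derived (e.g. model) frame, px.
#' @param transform The [frame_transform()] original -> derived frame.
#' @param axis `"row"` for vertical lengths, `"col"` for horizontal.
#' @return Length in original-image pixels.
#' @export
#' @examples
#' tr <- frame_transform(row_scale = 0.5, col_scale = 0.5)
#' map_length_to_original(61, tr, axis = "col") # 122
map_length_to_original <- function(length_px, transform, axis = c("col", "row")) {
  axis <- match.arg(axis)
  stopifnot(inherits(transform, "frame_transform"))
  s <- if (axis == "row") transform$row_scale else transform$col_scale
  length_px / s
}
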