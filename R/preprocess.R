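# Preprocessing: contrast-limited adaptive histogram equalization (CLAHE)
# and resizing to the model input frame with an invertible coordinate
# transform.
#
# CLAHE is implemented here (rather than delegated) because the package
# pins an exactly testable contract: per-tile clipped histogram
# equalization with bilinear blending between tile mappings, a clip limit
# expressed relative to the uniform bin height, conservation of per-tile
# histogram mass under redistribution, and the single-tile/infinite-clip
# configuration reducing to plain histogram equalization with the mapping
# m(g) = round(255 * cdf(g) / N). Tiles containing a single gray level map
# identically (no contrast to amplify), which makes CLAHE exactly
# idempotent on constant images.

to_gray <- function(image) {
  if (length(dim(image)) == 3) {
    # luminance from linear RGB weights
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  if (!is.matrix(image) || length(image) == 0) {
    stop_validation("image must be a non-empty matrix (or RGB array)")
  }
  image
}

# Clip a histogram at `limit` counts per bin and redistribute the excess
# uniformly, iterating so the redistributed mass never re-exceeds the limit;
# total mass is preserved.
clip_histogram <- function(h, limit) {
  if (!is.finite(limit)) return(h)
  for (pass in 1:32) {
    excess <- sum(pmax(h - limit, 0))
    if (excess <= 1e-9) break
    h <- pmin(h, limit)
    h <- h + excess / length(h)
  }
  h
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is padded (edge replication) to a whole number of tiles; each
#' tile's 256-bin histogram is clipped at `clip_limit` times the uniform bin
#' height (`tile_pixels / 256`), the clipped excess is redistributed
#' uniformly, and each pixel is remapped by bilinearly blending the
#' equalization mappings of the four nearest tile centres.
#'
#' @param image Numeric matrix on the 0..255 gray scale (RGB arrays are
#'   converted to luminance first).
#' @param clip_limit Clip limit relative to the uniform bin height;
#'   `Inf` disables clipping (plain adaptive equalization).
#' @param tile_grid `(rows, cols)` of contextual tiles; `c(1, 1)` with
#'   `clip_limit = Inf` is global histogram equalization.
#' @return Numeric matrix, same shape, integer gray values in `[0, 255]`.
#' @export
clahe <- function(image, clip_limit = 2, tile_grid = c(8, 8)) {
  image <- to_gray(image)
  if (!is.numeric(clip_limit) || is.na(clip_limit) || clip_limit <= 0) {
    stop_invalid("clip_limit must be positive (Inf allowed)")
  }
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2 || any(tile_grid < 1)) {
    stop_invalid("tile_grid must be two positive integers")
  }
  rows <- nrow(image); cols <- ncol(image)
  tr <- tile_grid[1]; tc <- tile_grid[2]
  th <- ceiling(rows / tr); tw <- ceiling(cols / tc)

  img <- round(pmin(pmax(image, 0), 255))
  # pad by edge replication to tr*th x tc*tw
  pad <- img[c(seq_len(rows), rep(rows, tr * th - rows)),
             c(seq_len(cols), rep(cols, tc * tw - cols)), drop = FALSE]

  n_tile <- th * tw
  limit <- clip_limit * n_tile / 256
  # per-tile LUTs: array (tr, tc, 256)
  lut <- array(0, c(tr, tc, 256))
  identity_lut <- 0:255
  for (a in seq_len(tr)) {
    for (b in seq_len(tc)) {
      tile <- pad[((a - 1) * th + 1):(a * th), ((b - 1) * tw + 1):(b * tw)]
      if (min(tile) == max(tile)) {
        lut[a, b, ] <- identity_lut
        next
      }
      h <- tabulate(tile + 1, nbins = 256)
      h <- clip_histogram(h, limit)
      lut[a, b, ] <- round(255 * cumsum(h) / sum(h))
    }
  }

  # bilinear blend between the mappings of the 4 nearest tile centres
  tile_coord <- function(idx, tsize, ntiles) {
    u <- (idx + 0.5) / tsize - 0.5
    t0 <- pmin(pmax(floor(u), 0), ntiles - 1)
    t1 <- pmin(t0 + 1, ntiles - 1)
    w <- u - floor(u)
    w[u < 0] <- 0
    w[u > ntiles - 1] <- 0
    list(t0 = t0 + 1, t1 = t1 + 1, w = w)
  }
  rc <- tile_coord(0:(rows - 1), th, tr)
  cc <- tile_coord(0:(cols - 1), tw, tc)

  g <- img + 1
  R0 <- rep(rc$t0, times = cols); R1 <- rep(rc$t1, times = cols)
  WR <- rep(rc$w, times = cols)
  C0 <- rep(cc$t0, each = rows); C1 <- rep(cc$t1, each = rows)
  WC <- rep(cc$w, each = rows)
  gv <- as.vector(g)
  v00 <- lut[cbind(R0, C0, gv)]; v01 <- lut[cbind(R0, C1, gv)]
  v10 <- lut[cbind(R1, C0, gv)]; v11 <- lut[cbind(R1, C1, gv)]
  out <- (1 - WR) * ((1 - WC) * v00 + WC * v01) +
    WR * ((1 - WC) * v10 + WC * v11)
  matrix(round(out), rows, cols)
}

#' Resize an image to the model input frame
#'
#' Bilinear resize (anisotropic when the input is not square) plus the
#' [frame_transform()] mapping original coordinates to the model frame,
#' aligned on pixel centres.
#'
#' @param image Numeric matrix (or RGB array, converted to luminance).
#' @param target `(rows, cols)` of the model frame; default 256 x 256.
#' @return List with `image` (resized matrix) and `transform`
#'   (original -> model frame).
#' @export
resize_to_model <- function(image, target = c(256, 256)) {
  image <- to_gray(image)
  target <- as.integer(target)
  if (length(target) != 2 || any(target < 1)) {
    stop_invalid("target must be (rows, cols) >= 1")
  }
  resized <- EBImage::resize(image, w = target[1], h = target[2],
                             filter = "bilinear")
  resized <- matrix(as.numeric(resized), target[1], target[2])
  sr <- target[1] / nrow(image); sc <- target[2] / ncol(image)
  # centre alignment: model = (orig + 0.5) * s - 0.5 = (orig - off) * s
  tr <- frame_transform(row_scale = sr, col_scale = sc,
                        row_offset = 0.5 * (1 - sr) / sr,
                        col_offset = 0.5 * (1 - sc) / sc)
  list(image = resized, transform = tr)
}
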