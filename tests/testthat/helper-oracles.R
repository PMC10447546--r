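# Independent oracles used across the suite. These deliberately use the
# most naive correct algorithm available (per-pixel ray casting, per-cutoff
# re-matching, direct CDF mapping) so they share no code path with the
# implementation they check.

# Even-odd point-in-polygon by ray casting along +col; vertices (row, col).
oracle_point_in_polygon <- function(row, col, vertices) {
  n <- nrow(vertices)
  crossings <- 0
  for (e in seq_len(n)) {
    r1 <- vertices[e, 1]; c1 <- vertices[e, 2]
    k <- if (e == n) 1 else e + 1
    r2 <- vertices[k, 1]; c2 <- vertices[k, 2]
    if ((r1 <= row && row < r2) || (r2 <= row && row < r1)) {
      x <- c1 + (row - r1) / (r2 - r1) * (c2 - c1)
      if (x > col) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

oracle_polygon_mask <- function(vertices, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (i in 0:(shape[1] - 1)) {
    for (j in 0:(shape[2] - 1)) {
      mask[i + 1, j + 1] <- oracle_point_in_polygon(i, j, vertices)
    }
  }
  mask
}

# Plain histogram equalization via direct CDF mapping, m(g) = round(255 *
# cdf(g) / N), for 0..255 integer images.
oracle_hist_equalize <- function(img) {
  counts <- tabulate(img + 1, nbins = 256)
  cdf <- cumsum(counts)
  lut <- round(255 * cdf / length(img))
  matrix(lut[img + 1], nrow(img), ncol(img))
}

# Rasterized disk: pixel centres within `radius` of the centre.
oracle_disk <- function(shape, cr, cc, radius) {
  rows <- 0:(shape[1] - 1); cols <- 0:(shape[2] - 1)
  outer((rows - cr)^2, (cols - cc)^2, `+`) <= radius^2
}

# Brute-force AP: enumerate every score cutoff, re-match greedily from
# scratch at each, then apply the interpolation to the resulting PR points.
oracle_average_precision <- function(detections, truths, iou_threshold,
                                     interpolation = "101") {
  greedy_match <- function(det) {
    det <- det[order(-det$score), , drop = FALSE]
    matched <- rep(FALSE, nrow(truths))
    tp <- 0
    for (i in seq_len(nrow(det))) {
      cand <- which(truths$image == det$image[i] & !matched)
      if (length(cand) == 0) next
      ious <- vapply(cand, function(j) box_iou(det[i, ], truths[j, ]), 0)
      b <- which.max(ious)
      if (ious[b] >= iou_threshold) { tp <- tp + 1; matched[cand[b]] <- TRUE }
    }
    tp
  }
  cutoffs <- sort(unique(detections$score), decreasing = TRUE)
  pr <- do.call(rbind, lapply(cutoffs, function(s) {
    sub <- detections[detections$score >= s, , drop = FALSE]
    tp <- greedy_match(sub)
    c(recall = tp / nrow(truths), precision = tp / nrow(sub))
  }))
  if (interpolation == "101") {
    grid <- seq(0, 1, by = 0.01)
    ap <- mean(vapply(grid, function(r) {
      p <- pr[pr[, "recall"] >= r, "precision"]
      if (length(p) == 0) 0 else max(p)
    }, 0))
  } else {
    rec <- pr[, "recall"]; prec <- pr[, "precision"]
    env <- rev(cummax(rev(prec)))
    ap <- sum((rec - c(0, rec[-length(rec)])) * env)
  }
  100 * ap
}

# Small scene used by many tests: modest magnification keeps rasters small.
tiny_scene <- function(..., magnification = 4) {
  make_scene(scene_params(magnification = magnification, ...))
}

# Ground-truth boxes of a scene list in detection-table form.
scene_truth_boxes <- function(scenes) {
  dplyr::bind_rows(lapply(seq_along(scenes), function(i) {
    dplyr::bind_rows(lapply(scenes[[i]]$eye_boxes, function(b) {
      tibble::tibble(image = i, row_min = b$row_min, col_min = b$col_min,
                     row_max = b$row_max, col_max = b$col_max)
    }))
  }))
}
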