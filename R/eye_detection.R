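# Eye-region detection and detection evaluation (AP50/AP75/mAP).
#
# The reference detector is deliberately classical and deterministic:
# intensity thresholding finds the two dark compact iris blobs, a bright
# connected component around each blob delimits the palpebral fissure (the
# annotated "eye box": eyelids above/below, canthi at the sides), and blob
# circularity provides the confidence score. Any learned detector can be
# slotted in instead: the plug-in contract is a function
# `image -> tibble(eye, row_min, col_min, row_max, col_max, score)`.

label_stats <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0) return(NULL)
  lab <- labels[idx]
  rr <- (idx - 1) %% nrow(labels)          # 0-based rows
  cc <- (idx - 1) %/% nrow(labels)         # 0-based cols
  # boundary pixels: any 4-neighbour outside the component
  n <- nrow(labels); m <- ncol(labels)
  padded <- matrix(0L, n + 2, m + 2)
  padded[2:(n + 1), 2:(m + 1)] <- labels
  core <- padded[2:(n + 1), 2:(m + 1)]
  boundary <- (padded[1:n, 2:(m + 1)] != core) |
    (padded[3:(n + 2), 2:(m + 1)] != core) |
    (padded[2:(n + 1), 1:m] != core) |
    (padded[2:(n + 1), 3:(m + 2)] != core)
  per <- tabulate(labels[boundary & labels > 0], nbins = max(lab))
  stats <- tibble::tibble(
    label = sort(unique(lab)),
    area = as.numeric(tabulate(lab, nbins = max(lab))[sort(unique(lab))]),
    perimeter = as.numeric(per[sort(unique(lab))])
  )
  cent <- rowsum(cbind(rr, cc), lab)
  stats$row_c <- cent[, 1] / stats$area
  stats$col_c <- cent[, 2] / stats$area
  bb <- tibble::tibble(
    row_min = as.numeric(tapply(rr, lab, min)),
    col_min = as.numeric(tapply(cc, lab, min)),
    row_max = as.numeric(tapply(rr, lab, max)),
    col_max = as.numeric(tapply(cc, lab, max))
  )
  dplyr::bind_cols(stats, bb)
}

#' Detect the two eye regions in a frontal image
#'
#' Classical reference detector: Otsu thresholding isolates dark compact
#' blobs (iris + pupil); candidates in the upper part of the image are
#' ranked by circularity (`4*pi*A/P^2`, clamped to `[0, 1]`) and the best
#' blob on each side of the midline is kept. The reported box is the
#' bounding box of the bright eye-opening component surrounding the blob
#' (eyelid aperture); if no such component exists the blob box expanded by
#' `margin_frac` of its width is used.
#'
#' @param image Numeric matrix (0..255 gray) or RGB array.
#' @param min_area Minimal candidate blob area, px.
#' @param margin_frac Fallback box expansion, as a fraction of blob width.
#' @return A tibble with one row per eye (`eye` = `"left"`, `"right"` in
#'   image order, i.e. left = smaller column), columns `row_min`,
#'   `col_min`, `row_max`, `col_max`, `score`.
#' @export
detect_eyes <- function(image, min_area = 20, margin_frac = 0.25) {
  img <- to_gray(image)
  rng <- range(img)
  if (diff(rng) < 1) {
    stop_detection("detection failed: image has no contrast (0 candidate blobs)")
  }
  thr_dark <- as.numeric(EBImage::otsu(EBImage::Image(img / 255))) * 255
  dark <- img < thr_dark
  labels <- EBImage::bwlabel(dark)
  stats <- label_stats(labels)
  if (!is.null(stats)) {
    stats <- dplyr::filter(stats, .data$area >= min_area,
                           .data$row_c < 0.65 * nrow(img))
  }
  n_found <- if (is.null(stats)) 0L else nrow(stats)
  if (n_found < 2) {
    stop_detection(sprintf(
      "detection failed: found %d candidate blob(s), need 2", n_found))
  }
  stats$circularity <- pmin(4 * pi * stats$area / stats$perimeter^2, 1)
  mid <- (ncol(img) - 1) / 2
  left  <- dplyr::slice_max(dplyr::filter(stats, .data$col_c <  mid),
                            .data$circularity, n = 1, with_ties = FALSE)
  right <- dplyr::slice_max(dplyr::filter(stats, .data$col_c >= mid),
                            .data$circularity, n = 1, with_ties = FALSE)
  if (nrow(left) == 0 || nrow(right) == 0) {
    stop_detection(sprintf(
      "detection failed: %d candidate blob(s) but not one on each side of the midline",
      n_found))
  }

  # bright eye-opening components (exclude any touching the border, e.g.
  # the background)
  thr_bright <- (stats::median(img) + max(img)) / 2
  bright <- img > thr_bright
  blab <- EBImage::bwlabel(bright)
  border_labels <- unique(c(blab[1, ], blab[nrow(blab), ],
                            blab[, 1], blab[, ncol(blab)]))
  bstats <- label_stats(blab)
  if (!is.null(bstats)) {
    bstats <- dplyr::filter(bstats, !(.data$label %in% border_labels))
  }

  eye_box <- function(blob) {
    if (!is.null(bstats) && nrow(bstats) > 0) {
      hit <- dplyr::filter(bstats,
                           .data$row_min <= blob$row_c, blob$row_c <= .data$row_max,
                           .data$col_min <= blob$col_c, blob$col_c <= .data$col_max)
      if (nrow(hit) > 0) {
        hit <- hit[which.max(hit$area), ]
        return(bbox(min(hit$row_min, blob$row_min),
                    min(hit$col_min, blob$col_min),
                    max(hit$row_max, blob$row_max),
                    max(hit$col_max, blob$col_max)))
      }
    }
    m <- margin_frac * (blob$col_max - blob$col_min + 1)
    bbox(max(blob$row_min - m, 0), max(blob$col_min - m, 0),
         min(blob$row_max + m, nrow(img) - 1),
         min(blob$col_max + m, ncol(img) - 1))
  }

  out <- purrr::map2(list(left, right), c("left", "right"), function(blob, side) {
    b <- eye_box(blob)
    tibble::tibble(eye = side, row_min = b$row_min, col_min = b$col_min,
                   row_max = b$row_max, col_max = b$col_max,
                   score = blob$circularity)
  })
  dplyr::bind_rows(out)
}

match_detections <- function(detections, truths, iou_threshold) {
  # returns detections ordered for the PR curve with a tp flag
  det <- dplyr::mutate(detections, .idx = dplyr::row_number())
  # tie-break score by best achievable IoU, then input order
  det$best_iou <- purrr::map_dbl(seq_len(nrow(det)), function(i) {
    tr <- truths[truths$image == det$image[i], , drop = FALSE]
    if (nrow(tr) == 0) return(0)
    max(purrr::map_dbl(seq_len(nrow(tr)),
                       function(j) box_iou(det[i, ], tr[j, ])))
  })
  det <- det[order(-det$score, -det$best_iou, det$.idx), ]
  matched <- rep(FALSE, nrow(truths))
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    cand <- which(truths$image == det$image[i] & !matched)
    if (length(cand) == 0) next
    ious <- purrr::map_dbl(cand, function(j) box_iou(det[i, ], truths[j, ]))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[i] <- TRUE
      matched[cand[best]] <- TRUE
    }
  }
  det$tp <- tp
  det
}

#' Average precision of a detection set
#'
#' Greedy score-ordered one-to-one matching (a ground-truth box is consumed
#' at most once; score ties broken by larger IoU, then input order),
#' followed by the area under the interpolated precision-recall curve.
#'
#' @param detections Tibble of detections: columns `image`, `row_min`,
#'   `col_min`, `row_max`, `col_max`, `score`.
#' @param truths Tibble of ground-truth boxes: `image` plus corner columns.
#' @param iou_threshold Matching IoU threshold (e.g. 0.5 for AP50).
#' @param interpolation `"101"` for 101-point interpolation (default) or
#'   `"all"` for all-point (area under the precision envelope).
#' @return AP in percent (0..100).
#' @export
average_precision <- function(detections, truths, iou_threshold = 0.5,
                              interpolation = c("101", "all")) {
  interpolation <- match.arg(interpolation)
  if (is.null(truths) || nrow(truths) == 0) {
    stop_undefined_metric("average precision is undefined for an empty truth set")
  }
  if (is.null(detections) || nrow(detections) == 0) return(0)
  det <- match_detections(detections, truths, iou_threshold)
  tp_cum <- cumsum(det$tp)
  fp_cum <- cumsum(!det$tp)
  recall <- tp_cum / nrow(truths)
  precision <- tp_cum / (tp_cum + fp_cum)
  if (interpolation == "101") {
    grid <- seq(0, 1, by = 0.01)
    ap <- mean(purrr::map_dbl(grid, function(r) {
      p <- precision[recall >= r]
      if (length(p) == 0) 0 else max(p)
    }))
  } else {
    # precision envelope over distinct recall steps
    env <- rev(cummax(rev(precision)))
    r_prev <- c(0, recall[-length(recall)])
    ap <- sum((recall - r_prev) * env)
  }
  100 * ap
}

#' Detection metrics at several IoU thresholds
#'
#' @inheritParams average_precision
#' @param thresholds IoU thresholds; defaults to 0.5 and 0.75 (AP50, AP75).
#' @return An object of class `iriscal_detection_metrics`: tibble of per-
#'   threshold AP plus the mAP (their mean). Use [generics::tidy()] /
#'   [generics::glance()] to extract.
#' @export
detection_metrics <- function(detections, truths,
                              thresholds = c(0.5, 0.75),
                              interpolation = c("101", "all")) {
  interpolation <- match.arg(interpolation)
  ap <- purrr::map_dbl(thresholds, function(t) {
    average_precision(detections, truths, t, interpolation)
  })
  structure(
    list(ap_by_threshold = tibble::tibble(iou_threshold = thresholds, ap = ap),
         map = mean(ap)),
    class = "iriscal_detection_metrics"
  )
}

#' @export
print.iriscal_detection_metrics <- function(x, ...) {
  cat("Detection metrics\n")
  for (i in seq_len(nrow(x$ap_by_threshold))) {
    cat(sprintf("  AP%.0f = %.3f\n", 100 * x$ap_by_threshold$iou_threshold[i],
                x$ap_by_threshold$ap[i]))
  }
  cat(sprintf("  mAP  = %.3f\n", x$map))
  invisible(x)
}

#' @export
tidy.iriscal_detection_metrics <- function(x, ...) x$ap_by_threshold

#' @export
glance.iriscal_detection_metrics <- function(x, ...) {
  tibble::tibble(map = x$map)
}

#' Evaluate a detector on synthetic scenes
#'
#' Runs the detector on each rendered scene and scores the returned boxes
#' against the scenes' ground-truth eye boxes.
#'
#' @param scenes List of rendered `synthetic_scene`s.
#' @param detector Plug-in detector `image -> detection tibble`; defaults
#'   to [detect_eyes()].
#' @param thresholds IoU thresholds.
#' @param interpolation AP interpolation convention.
#' @return `iriscal_detection_metrics`.
#' @export
evaluate_detector <- function(scenes, detector = detect_eyes,
                              thresholds = c(0.5, 0.75),
                              interpolation = c("101", "all")) {
  interpolation <- match.arg(interpolation)
  dets <- list(); trs <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    d <- detector(sc$image)
    d$image <- i
    dets[[i]] <- d
    trs[[i]] <- dplyr::bind_rows(purrr::map(sc$eye_boxes, function(b) {
      tibble::tibble(image = i, row_min = b$row_min, col_min = b$col_min,
                     row_max = b$row_max, col_max = b$col_max)
    }))
  }
  detection_metrics(dplyr::bind_rows(dets), dplyr::bind_rows(trs),
                    thresholds, interpolation)
}
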