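# Iris segmentation and mask-level evaluation.
#
# The reference segmenter is a deterministic classical pipeline (Otsu
# threshold -> morphological opening/closing -> largest connected component
# -> hole filling); the evaluation harness accepts any drop-in segmenter
# with the contract `roi_image -> logical matrix`, so externally produced
# masks (e.g. from a trained network) can be scored identically.

#' Segment the iris in an eye ROI
#'
#' @param roi_image Numeric matrix (0..255 gray), one eye per ROI, ideally
#'   CLAHE-preprocessed.
#' @param opening_radius,closing_radius Disc radii (px) for morphological
#'   opening (removes specks) and closing (bridges the eyelid notch).
#' @return Logical matrix in the ROI frame.
#' @export
segment_iris <- function(roi_image, opening_radius = 2, closing_radius = 2) {
  img <- to_gray(roi_image)
  if (diff(range(img)) < 1) {
    stop_segmentation("segmentation failed: ROI has no contrast")
  }
  thr <- as.numeric(EBImage::otsu(EBImage::Image(img / 255))) * 255
  fg <- img < thr                      # the iris is the dark structure
  if (opening_radius > 0) {
    fg <- EBImage::opening(fg, EBImage::makeBrush(2 * opening_radius + 1, "disc"))
  }
  if (closing_radius > 0) {
    fg <- EBImage::closing(fg, EBImage::makeBrush(2 * closing_radius + 1, "disc"))
  }
  labels <- EBImage::bwlabel(fg > 0)
  if (max(labels) == 0) {
    stop_segmentation("segmentation failed: empty foreground after filtering")
  }
  areas <- tabulate(labels[labels > 0])
  keep <- which.max(areas)
  mask <- labels == keep
  mask <- EBImage::fillHull(mask) > 0   # the pupil is iris, not a hole
  matrix(as.logical(mask), nrow(img), ncol(img))
}

#' Pixel-wise confusion counts between two masks
#'
#' @param pred,truth Logical matrices of identical shape.
#' @return One-row tibble `tp`, `fp`, `fn`, `tn` (pixel counts).
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop_validation("prediction and truth masks differ in shape")
  }
  tp <- sum(pred & truth)
  tibble::tibble(
    tp = tp,
    fp = sum(pred) - tp,
    fn = sum(truth) - tp,
    tn = length(pred) - sum(pred | truth)
  )
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy, Dice coefficient, IoU, precision and recall in percent, plus
#' the Jaccard distance `1 - IoU` as a unitless fraction. A metric whose
#' denominator is zero is reported as `NaN` (flagged undefined rather than
#' silently 0); all-zero counts are an error.
#'
#' @param counts One-row tibble/list with `tp`, `fp`, `fn`, `tn`.
#' @return One-row tibble `accuracy`, `dice`, `iou`, `precision`, `recall`
#'   (percent) and `jaccard_distance` (fraction).
#' @export
segmentation_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (any(c(tp, fp, fn, tn) < 0)) stop_validation("negative confusion counts")
  total <- tp + fp + fn + tn
  if (total == 0) stop_undefined_metric("all confusion counts are zero")
  frac <- function(num, den) if (den > 0) num / den else NaN
  iou_frac <- frac(tp, tp + fp + fn)
  tibble::tibble(
    accuracy = 100 * frac(tp + tn, total),
    dice = 100 * frac(2 * tp, (tp + fp) + (tp + fn)),
    iou = 100 * iou_frac,
    precision = 100 * frac(tp, tp + fp),
    recall = 100 * frac(tp, tp + fn),
    jaccard_distance = 1 - iou_frac
  )
}

#' k-fold cross-validation splits
#'
#' Validation folds are disjoint, their union covers all items, and sizes
#' differ by at most one; the shuffle is deterministic under `seed`.
#'
#' @param items Vector/list of items (only the length is used) or a count.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return List of `k` lists, each with `train` and `validation` integer
#'   index vectors (1-based).
#' @export
cross_validation_folds <- function(items, k = 5, seed = 1L) {
  n <- if (length(items) == 1 && is.numeric(items)) as.integer(items) else length(items)
  if (k < 2) stop_invalid("k must be >= 2")
  if (k > n) stop_invalid(sprintf("k = %d exceeds the number of items (%d)", k, n))
  idx <- withr::with_seed(as.integer(seed), sample.int(n))
  fold_id <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) {
    val <- sort(idx[fold_id == f])
    list(train = setdiff(seq_len(n), val), validation = val)
  })
}

# Extract one eye ROI (image + ground-truth mask) from a scene, in the
# model frame. Returns list(roi, truth, transform).
scene_eye_roi <- function(scene, side, target = c(256, 256),
                          margin_frac = 0.15, apply_clahe = TRUE) {
  box <- scene$eye_boxes[[side]]
  margin <- margin_frac * (box$col_max - box$col_min + 1)
  crop <- crop_roi(scene$image, box, margin = margin)
  rs <- resize_to_model(crop$image, target = target)
  roi <- if (apply_clahe) clahe(rs$image) else rs$image
  truth <- NULL
  if (!is.null(scene$iris_masks)) {
    mcrop <- crop_roi(scene$iris_masks[[side]], box, margin = margin)
    tmask <- EBImage::resize(mcrop$image * 1.0, w = target[1], h = target[2],
                             filter = "bilinear")
    truth <- matrix(as.numeric(tmask), target[1], target[2]) >= 0.5
  }
  list(roi = roi, truth = truth,
       transform = compose_transforms(crop$transform, rs$transform))
}

#' Evaluate a segmenter over cross-validation folds
#'
#' Each scene contributes two eye ROIs; metrics are computed per ROI in the
#' model frame against the scene's rasterized ground truth, averaged within
#' each validation fold, and summarized as mean +/- SD across folds (the
#' layout of a model-comparison table). Segmentation failures propagate as
#' per-item `NA`s and are counted, never imputed.
#'
#' @param scenes List of rendered `synthetic_scene`s.
#' @param segmenter Plug-in segmenter `roi_image -> logical matrix`;
#'   defaults to [segment_iris()]. Pass `oracle_segmenter(scenes)` to score
#'   the ground truth against itself.
#' @param folds Folds over the ROI items (2 per scene), as from
#'   [cross_validation_folds()]; default five folds, seed 1.
#' @param target Model frame size.
#' @param apply_clahe Apply [clahe()] to each ROI before segmenting.
#' @return `iriscal_segmentation_eval`: list with `per_item`, `per_fold`,
#'   `summary` tibbles and `n_failures`.
#' @export
evaluate_segmenter <- function(scenes, segmenter = segment_iris, folds = NULL,
                               target = c(256, 256), apply_clahe = TRUE) {
  items <- tidyr::expand_grid(scene = seq_along(scenes),
                              side = c("left", "right"))
  if (is.null(folds)) folds <- cross_validation_folds(nrow(items), k = 5, seed = 1L)
  metric_names <- c("accuracy", "dice", "iou", "precision", "recall",
                    "jaccard_distance")

  per_item <- purrr::map_dfr(seq_len(nrow(items)), function(i) {
    sc <- scenes[[items$scene[i]]]
    er <- scene_eye_roi(sc, items$side[i], target = target,
                        apply_clahe = apply_clahe)
    attr(er$roi, "truth") <- er$truth
    res <- tryCatch({
      pred <- segmenter(er$roi)
      segmentation_metrics(confusion_counts(pred, er$truth))
    }, iriscal_segmentation_failure = function(e) {
      tibble::as_tibble(stats::setNames(
        as.list(rep(NA_real_, length(metric_names))), metric_names))
    })
    dplyr::bind_cols(items[i, ], res)
  })

  fold_of_item <- integer(nrow(items))
  for (f in seq_along(folds)) fold_of_item[folds[[f]]$validation] <- f
  per_item$fold <- fold_of_item

  per_fold <- per_item |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_names),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_failures = sum(is.na(.data$dice)), .groups = "drop")
  summary <- per_fold |>
    tidyr::pivot_longer(dplyr::all_of(metric_names),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")

  structure(list(per_item = per_item, per_fold = per_fold, summary = summary,
                 n_failures = sum(per_fold$n_failures)),
            class = "iriscal_segmentation_eval")
}

#' Oracle segmenter (ground-truth pass-through)
#'
#' Inside [evaluate_segmenter()] every ROI carries its ground-truth mask as
#' the `"truth"` attribute; this segmenter simply returns it. Scoring the
#' oracle isolates harness error (exactly zero) from model error, and gives
#' the expected 100%-everywhere reference row.
#'
#' @param roi_image ROI as passed to a plug-in segmenter.
#' @return The ground-truth logical matrix.
#' @export
oracle_segmenter <- function(roi_image) {
  truth <- attr(roi_image, "truth")
  if (is.null(truth)) {
    stop_segmentation("oracle segmenter: ROI carries no ground truth")
  }
  truth
}

#' Empty segmenter (all-background baseline)
#'
#' @param roi_image ROI as passed to a plug-in segmenter.
#' @return All-`FALSE` mask of the ROI's shape.
#' @export
empty_segmenter <- function(roi_image) {
  matrix(FALSE, nrow(roi_image), ncol(roi_image))
}

#' @export
print.iriscal_segmentation_eval <- function(x, ...) {
  cat("Segmentation evaluation (mean +/- SD across folds)\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-17s %8.3f (+/- %.4f)\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  if (x$n_failures > 0) cat(sprintf("  failures: %d\n", x$n_failures))
  invisible(x)
}

#' @export
tidy.iriscal_segmentation_eval <- function(x, ...) x$per_fold

#' @export
glance.iriscal_segmentation_eval <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  tibble::as_tibble(c(wide, list(n_failures = x$n_failures)))
}

#' Consistency validator for published segmentation tables
#'
#' Checks each row of a model-comparison table for the internal identity
#' Jaccard distance = 1 - IoU, within the rounding tolerance of the printed
#' figures.
#'
#' @param df Data frame with columns `iou` (percent) and
#'   `jaccard_distance` (fraction).
#' @param tolerance Allowed absolute discrepancy (default 2e-4: one
#'   half-ulp of each printed figure plus slack).
#' @return The input with `implied_jaccard`, `discrepancy` and `consistent`
#'   columns appended.
#' @export
validate_segmentation_summary <- function(df, tolerance = 2e-4) {
  df |>
    dplyr::mutate(
      implied_jaccard = 1 - .data$iou / 100,
      discrepancy = abs(.data$implied_jaccard - .data$jaccard_distance),
      consistent = .data$discrepancy <= tolerance
    )
}
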