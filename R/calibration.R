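# Iris-dependent calibration: the core computation.
#
# The horizontal visible iris diameter (HVID) is measured in pixels, a
# constant anatomical value (default 12.2 mm) is assigned to it, and the
# mm-per-px ratio assigned_mm / hvid_px scales every pixel-space landmark
# distance to millimetres. HVID is defined as the maximal horizontal chord
# of the iris mask: this matches the "horizontal visible" semantics and is
# invariant to upper/lower eyelid occlusion as long as the iris equator
# stays visible.

#' Horizontal visible iris diameter of a mask, in pixels
#'
#' The maximal horizontal chord: the maximum over rows of
#' (rightmost member column - leftmost member column + 1).
#'
#' @param mask Logical matrix (original-image pixel units; map model-frame
#'   measurements back first, see [map_length_to_original()]).
#' @return HVID in pixels (positive integer).
#' @export
#' @examples
#' m <- matrix(FALSE, 12, 50); m[4:9, 6 + 0:39] <- TRUE
#' hvid_pixels(m) # 40
hvid_pixels <- function(mask) {
  if (!is.matrix(mask)) stop_validation("mask must be a logical matrix")
  if (!any(mask)) stop_validation("cannot measure HVID of an empty mask")
  max(row_spans(mask))
}

#' Magnification ratio from the two eyes' HVID
#'
#' Divides the assigned iris diameter in millimetres by its measured
#' diameter in pixels. The two eyes are combined according to
#' `combine` (default: the mean of the two pixel diameters, giving one
#' magnification per photograph).
#'
#' @param hvid_left,hvid_right HVID of each eye, px.
#' @param assigned_mm Assigned anatomical HVID, mm (default 12.2).
#' @param combine `"mean"` (mean of pixel diameters), `"left"`, `"right"`,
#'   or `"per_eye_mean_of_ratios"` (mean of the two per-eye ratios).
#' @return A `calibration_result`: `hvid_px_left`, `hvid_px_right`,
#'   `hvid_px_used`, `assigned_hvid_mm`, `ratio_mm_per_px`.
#' @export
#' @examples
#' magnification_ratio(61, 61, 12.2)$ratio_mm_per_px # 0.2
magnification_ratio <- function(hvid_left, hvid_right, assigned_mm = 12.2,
                                combine = c("mean", "left", "right",
                                            "per_eye_mean_of_ratios")) {
  combine <- match.arg(combine)
  if (!is.finite(hvid_left) || !is.finite(hvid_right) ||
      hvid_left <= 0 || hvid_right <= 0) {
    stop_invalid("HVID pixel values must be positive")
  }
  if (!is.finite(assigned_mm) || assigned_mm <= 0) {
    stop_invalid("assigned_mm must be positive")
  }
  ratio <- switch(combine,
    mean = assigned_mm / mean(c(hvid_left, hvid_right)),
    left = assigned_mm / hvid_left,
    right = assigned_mm / hvid_right,
    per_eye_mean_of_ratios =
      mean(c(assigned_mm / hvid_left, assigned_mm / hvid_right))
  )
  structure(
    list(hvid_px_left = hvid_left, hvid_px_right = hvid_right,
         hvid_px_used = assigned_mm / ratio,
         assigned_hvid_mm = assigned_mm,
         ratio_mm_per_px = ratio, combine = combine),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration: HVID (%.2f, %.2f) px, assigned %.2f mm, ratio %.5f mm/px>\n",
    x$hvid_px_left, x$hvid_px_right, x$assigned_hvid_mm, x$ratio_mm_per_px))
  invisible(x)
}

#' @export
tidy.calibration_result <- function(x, ...) {
  tibble::tibble(hvid_px_left = x$hvid_px_left,
                 hvid_px_right = x$hvid_px_right,
                 hvid_px_used = x$hvid_px_used,
                 assigned_hvid_mm = x$assigned_hvid_mm,
                 ratio_mm_per_px = x$ratio_mm_per_px)
}

#' Scale a pixel distance to millimetres
#'
#' @param distance_px Distance(s) in pixels (vectorized).
#' @param cal A `calibration_result`.
#' @return Distance(s) in millimetres.
#' @export
estimate_mm <- function(distance_px, cal) {
  stopifnot(inherits(cal, "calibration_result"))
  if (any(distance_px < 0)) stop_invalid("distances must be >= 0")
  distance_px * cal$ratio_mm_per_px
}

#' Oracle measurement of a scene (ground truth pass-through)
#'
#' Uses the stored pre-rasterization iris diameter and the exact landmark
#' pixel coordinates; isolates the statistics of the calibration itself
#' from detector/segmenter error.
#'
#' @param scene A `synthetic_scene` (rendered or not).
#' @return List with `hvid_px` (named left/right) and `distances_px`
#'   (named `lateral_canthi`, `subnasale_submental`).
#' @export
measure_scene_oracle <- function(scene) {
  lm <- scene$landmarks_px
  pt <- function(nm) unlist(lm[lm$name == nm, c("row", "col")])
  list(
    hvid_px = c(left = scene$iris_diameter_px,
                right = scene$iris_diameter_px),
    distances_px = c(
      lateral_canthi = pixel_distance(pt("left_canthus"), pt("right_canthus")),
      subnasale_submental = pixel_distance(pt("subnasale"), pt("submental"))
    )
  )
}

#' Reference measurement of a scene (full classical pipeline)
#'
#' CLAHE -> eye detection -> ROI crop -> resize to the model frame ->
#' CLAHE -> iris segmentation -> maximal horizontal chord mapped back to
#' original pixels. Landmark distances come from the scene's annotation
#' (landmarks are annotated inputs, not detected).
#'
#' @param scene A rendered `synthetic_scene`.
#' @param detector Plug-in detector (default [detect_eyes()]).
#' @param segmenter Plug-in segmenter (default [segment_iris()]).
#' @param target Model frame size for segmentation.
#' @param clahe_detection,clahe_segmentation Apply CLAHE before the
#'   respective stage.
#' @param roi_margin_frac ROI margin as a fraction of the eye-box width.
#' @return Same shape as [measure_scene_oracle()].
#' @export
measure_scene_reference <- function(scene, detector = detect_eyes,
                                    segmenter = segment_iris,
                                    target = c(256, 256),
                                    clahe_detection = TRUE,
                                    clahe_segmentation = TRUE,
                                    roi_margin_frac = 0.15) {
  if (is.null(scene$image)) stop_validation("scene was generated with render = FALSE")
  img <- to_gray(scene$image)
  det_img <- if (clahe_detection) clahe(img) else img
  det <- detector(det_img)

  hvid <- purrr::map_dbl(c("left", "right"), function(side) {
    box <- as_bbox(det[det$eye == side, ])
    margin <- roi_margin_frac * (box$col_max - box$col_min + 1)
    crop <- crop_roi(img, box, margin = margin)
    rs <- resize_to_model(crop$image, target = target)
    roi <- if (clahe_segmentation) clahe(rs$image) else rs$image
    mask <- segmenter(roi)
    chord_model <- hvid_pixels(mask)
    map_length_to_original(chord_model, rs$transform, axis = "col")
  })

  lm <- scene$landmarks_px
  pt <- function(nm) unlist(lm[lm$name == nm, c("row", "col")])
  list(
    hvid_px = c(left = hvid[1], right = hvid[2]),
    distances_px = c(
      lateral_canthi = pixel_distance(pt("left_canthus"), pt("right_canthus")),
      subnasale_submental = pixel_distance(pt("subnasale"), pt("submental"))
    )
  )
}

#' Sweep the assigned HVID value over a grid
#'
#' For every candidate assigned HVID, estimates both landmark distances on
#' every scene through the calibration ratio and records the mean absolute
#' percentage error per dimension; reports the grid value minimizing the
#' mean MAPE (ties broken toward the smaller value). Scenes failing
#' measurement are excluded and counted; more than 20% exclusions abort.
#'
#' @param scenes List of `synthetic_scene`s (>= 2).
#' @param pipeline Measurement function `scene -> list(hvid_px,
#'   distances_px)`; [measure_scene_oracle()] (default) or
#'   [measure_scene_reference()].
#' @param grid Strictly increasing assigned-HVID values, mm; default
#'   10.5 to 13.5 in 0.1 mm steps.
#' @param combine Eye-combination rule, see [magnification_ratio()].
#' @return `iriscal_sweep`: `curve` tibble (`assigned_mm`,
#'   `mape_horizontal`, `mape_vertical`, `mape_mean`), `argmin_mm`,
#'   `n_scenes`, `n_excluded`.
#' @export
sweep_assigned_hvid <- function(scenes, pipeline = measure_scene_oracle,
                                grid = seq(10.5, 13.5, by = 0.1),
                                combine = "mean") {
  if (length(scenes) < 2) stop_invalid("need at least 2 scenes")
  if (length(grid) == 0 || any(diff(grid) <= 0)) {
    stop_invalid("grid must be non-empty and strictly increasing")
  }
  meas <- purrr::map(scenes, function(sc) {
    tryCatch(c(pipeline(sc), list(truth = sc$true_distances_mm)),
             iriscal_detection_failure = function(e) NULL,
             iriscal_segmentation_failure = function(e) NULL)
  })
  ok <- !purrr::map_lgl(meas, is.null)
  n_excluded <- sum(!ok)
  if (n_excluded > 0.2 * length(scenes)) {
    stop_validation(sprintf(
      "%d of %d scenes failed measurement (> 20%%)", n_excluded, length(scenes)))
  }
  meas <- meas[ok]

  hvid_used <- purrr::map_dbl(meas, function(m) {
    magnification_ratio(m$hvid_px[["left"]], m$hvid_px[["right"]],
                        assigned_mm = 1, combine = combine)$hvid_px_used
  })
  d_h <- purrr::map_dbl(meas, ~ .x$distances_px[["lateral_canthi"]])
  d_v <- purrr::map_dbl(meas, ~ .x$distances_px[["subnasale_submental"]])
  t_h <- purrr::map_dbl(meas, ~ .x$truth[["lateral_canthi"]])
  t_v <- purrr::map_dbl(meas, ~ .x$truth[["subnasale_submental"]])

  curve <- purrr::map_dfr(grid, function(a) {
    ratio <- a / hvid_used
    tibble::tibble(
      assigned_mm = a,
      mape_horizontal = 100 * mean(abs(t_h - d_h * ratio) / t_h),
      mape_vertical = 100 * mean(abs(t_v - d_v * ratio) / t_v)
    )
  })
  curve$mape_mean <- (curve$mape_horizontal + curve$mape_vertical) / 2
  argmin <- curve$assigned_mm[which.min(curve$mape_mean)]

  structure(list(curve = curve, argmin_mm = argmin,
                 n_scenes = length(scenes), n_excluded = n_excluded),
            class = "iriscal_sweep")
}

#' @export
print.iriscal_sweep <- function(x, ...) {
  cat(sprintf(
    "<assigned-HVID sweep over [%.1f, %.1f] mm, %d scenes (%d excluded)>\n",
    min(x$curve$assigned_mm), max(x$curve$assigned_mm),
    x$n_scenes, x$n_excluded))
  cat(sprintf("  argmin %.1f mm (mean MAPE %.3f%%)\n", x$argmin_mm,
              min(x$curve$mape_mean)))
  invisible(x)
}

#' @export
tidy.iriscal_sweep <- function(x, ...) x$curve

#' @export
glance.iriscal_sweep <- function(x, ...) {
  tibble::tibble(argmin_mm = x$argmin_mm,
                 min_mape = min(x$curve$mape_mean),
                 n_scenes = x$n_scenes, n_excluded = x$n_excluded)
}
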