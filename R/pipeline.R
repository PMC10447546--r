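# End-to-end orchestration: preprocess -> detect -> segment -> calibrate ->
# estimate -> report, over either a directory of images + annotations or a
# synthetic population, driven by a single config.

#' Default pipeline configuration
#'
#' Returns the full nested configuration with every tunable of the
#' pipeline. User configs (YAML) are merged over these defaults, so a
#' config file only needs to state what it changes.
#'
#' @return Nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    input_mode = "synthetic",          # "images" or "synthetic"
    paths = list(image_dir = NULL, truth_csv = NULL),
    synthetic = list(
      n = 50, hvid_mean = 12.2, hvid_sd = 0.49,
      magnification_range = c(3, 8),
      distance_ranges = list(lateral_canthi = c(88, 110.7),
                             subnasale_submental = c(47.25, 86)),
      occlusion_max = 0.2, noise_sd = 0
    ),
    clahe = list(clip_limit = 2, tile_grid = c(8, 8)),
    model = list(input_size = c(256, 256)),
    detection = list(min_area = 20, margin_frac = 0.25, apply_clahe = TRUE),
    segmentation = list(opening_radius = 2, closing_radius = 2,
                        apply_clahe = TRUE, roi_margin_frac = 0.15),
    calibration = list(assigned_hvid_mm = 12.2, eye_combination = "mean"),
    sweep = list(grid_min = 10.5, grid_max = 13.5, grid_step = 0.1,
                 pipeline = "oracle")   # "oracle" or "reference"
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline config file (YAML), merged over the defaults
#'
#' @param path YAML file; `NULL` returns [default_config()].
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_io(sprintf("config file '%s' not found", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (is.null(cfg$calibration$assigned_hvid_mm) ||
      cfg$calibration$assigned_hvid_mm <= 0) {
    stop_invalid("calibration.assigned_hvid_mm must be > 0")
  }
  if (!cfg$input_mode %in% c("images", "synthetic")) {
    stop_invalid("input_mode must be 'images' or 'synthetic'")
  }
  cfg
}

config_measurer <- function(config) {
  function(scene) {
    measure_scene_reference(
      scene,
      detector = function(img) detect_eyes(
        img, min_area = config$detection$min_area,
        margin_frac = config$detection$margin_frac),
      segmenter = function(roi) segment_iris(
        roi, opening_radius = config$segmentation$opening_radius,
        closing_radius = config$segmentation$closing_radius),
      target = config$model$input_size,
      clahe_detection = config$detection$apply_clahe,
      clahe_segmentation = config$segmentation$apply_clahe,
      roi_margin_frac = config$segmentation$roi_margin_frac
    )
  }
}

# Iterate subjects in either input mode, calling fn(subject_id, scene-like)
# where the scene-like object has $image, $landmarks_px; synthetic subjects
# are full scenes built lazily (one at a time, so populations of hundreds
# never hold all rasters in memory).
subject_stream <- function(config) {
  if (config$input_mode == "synthetic") {
    syn <- config$synthetic
    pars <- sample_population_params(
      n = syn$n, hvid_mean = syn$hvid_mean, hvid_sd = syn$hvid_sd,
      magnification_range = syn$magnification_range,
      distance_ranges = syn$distance_ranges,
      occlusion_max = syn$occlusion_max, noise_sd = syn$noise_sd,
      seed = config$seed)
    list(
      ids = pars$subject_id,
      truth = tibble::tibble(
        subject_id = pars$subject_id,
        lateral_canthi_mm = pars$canthal_distance_mm,
        subnasale_submental_mm = pars$subnasale_submental_mm),
      get = function(i) {
        sc <- make_scene(scene_params(
          hvid_mm = pars$hvid_mm[i], magnification = pars$magnification[i],
          canthal_distance_mm = pars$canthal_distance_mm[i],
          subnasale_submental_mm = pars$subnasale_submental_mm[i],
          occlusion_fraction = pars$occlusion_fraction[i],
          noise_sd = pars$noise_sd[i], seed = pars$seed[i]))
        sc$subject_id <- pars$subject_id[i]
        sc
      }
    )
  } else {
    dir <- config$paths$image_dir
    if (is.null(dir) || !dir.exists(dir)) {
      stop_io("paths.image_dir missing or not a directory")
    }
    jsons <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
    ids <- sub("\\.json$", "", basename(jsons))
    truth <- NULL
    tc <- config$paths$truth_csv
    if (!is.null(tc) && file.exists(tc)) {
      truth <- readr::read_csv(tc, show_col_types = FALSE)
    } else {
      pooled <- file.path(dir, "truth.csv")
      if (file.exists(pooled)) truth <- readr::read_csv(pooled,
                                                        show_col_types = FALSE)
    }
    list(
      ids = ids,
      truth = truth,
      get = function(i) {
        img_path <- file.path(dir, paste0(ids[i], ".png"))
        if (!file.exists(img_path)) stop_io(sprintf("image '%s' missing", img_path))
        raster <- png::readPNG(img_path)
        if (length(dim(raster)) == 3) raster <- to_gray(raster * 255) else
          raster <- raster * 255
        ann <- read_labelme(file.path(dir, paste0(ids[i], ".json")))
        list(image = raster, landmarks_px = ann$landmarks,
             subject_id = ids[i])
      }
    )
  }
}

#' Run the estimation pipeline over all subjects
#'
#' For each subject: CLAHE, eye detection, ROI crop, iris segmentation,
#' HVID in original pixels, magnification ratio from the assigned HVID, and
#' millimetre estimates of both landmark distances. Subjects failing
#' detection or segmentation are logged and skipped, never imputed; every
#' subject appears exactly once in either the results or the failure log.
#'
#' @param config Configuration list (see [default_config()] /
#'   [read_config()]).
#' @param out_dir Optional directory: writes `results.csv`, `failures.csv`
#'   and a JSON run manifest.
#' @return List with `results` (tibble: one row per subject x dimension),
#'   `calibrations` (tibble: one row per subject), `failures` (tibble),
#'   `truth` (tibble or NULL), `config`.
#' @export
run_estimate <- function(config = default_config(), out_dir = NULL) {
  stream <- subject_stream(config)
  measure <- config_measurer(config)
  assigned <- config$calibration$assigned_hvid_mm
  combine <- config$calibration$eye_combination

  res_rows <- list(); cal_rows <- list(); fail_rows <- list()
  for (i in seq_along(stream$ids)) {
    id <- stream$ids[i]
    out <- tryCatch({
      subject <- stream$get(i)
      m <- measure(subject)
      cal <- magnification_ratio(m$hvid_px[["left"]], m$hvid_px[["right"]],
                                 assigned_mm = assigned, combine = combine)
      list(m = m, cal = cal)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      stage <- dplyr::case_when(
        inherits(out, "iriscal_detection_failure") ~ "detection",
        inherits(out, "iriscal_segmentation_failure") ~ "segmentation",
        TRUE ~ "other")
      fail_rows[[id]] <- tibble::tibble(subject_id = id, stage = stage,
                                        message = conditionMessage(out))
      next
    }
    cal_rows[[id]] <- dplyr::bind_cols(tibble::tibble(subject_id = id),
                                       tidy(out$cal))
    res_rows[[id]] <- tibble::tibble(
      subject_id = id,
      dimension = c("horizontal", "vertical"),
      measurement = c("lateral_canthi", "subnasale_submental"),
      distance_px = as.numeric(out$m$distances_px[
        c("lateral_canthi", "subnasale_submental")]),
      predicted_mm = estimate_mm(.data$distance_px, out$cal)
    )
  }
  if (length(res_rows) == 0) {
    fails <- dplyr::bind_rows(fail_rows)
    stop_validation(sprintf(
      "no subject processed successfully (%d failures: %s)",
      nrow(fails), paste(unique(fails$stage), collapse = ", ")))
  }
  out <- list(
    results = dplyr::bind_rows(res_rows),
    calibrations = dplyr::bind_rows(cal_rows),
    failures = if (length(fail_rows)) dplyr::bind_rows(fail_rows) else
      tibble::tibble(subject_id = character(), stage = character(),
                     message = character()),
    truth = stream$truth,
    config = config
  )
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

write_run_outputs <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(run$results, file.path(out_dir, "results.csv"))
  readr::write_csv(run$failures, file.path(out_dir, "failures.csv"))
  manifest <- list(
    package = "iriscal",
    version = as.character(utils::packageVersion("iriscal")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = run$config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the validation study: estimates vs actual measurements
#'
#' Joins pipeline predictions with the actual millimetre distances
#' (synthetic ground truth, or the caliper table in images mode) and emits
#' the full error report. Unmatched subjects are listed; more than 10%
#' unmatched is an error.
#'
#' @inheritParams run_estimate
#' @return List with `report` (an `iriscal_error_report`), `pairs`,
#'   `comparison` (distribution comparison tibble), `run` (the
#'   [run_estimate()] output).
#' @export
run_validation <- function(config = default_config(), out_dir = NULL) {
  run <- run_estimate(config)
  if (is.null(run$truth)) {
    stop_validation("no actual measurements available (truth table missing)")
  }
  truth_long <- run$truth |>
    tidyr::pivot_longer(c("lateral_canthi_mm", "subnasale_submental_mm"),
                        names_to = "measurement", values_to = "actual_mm") |>
    dplyr::mutate(measurement = sub("_mm$", "", .data$measurement))
  pairs <- dplyr::inner_join(run$results, truth_long,
                             by = c("subject_id", "measurement")) |>
    dplyr::select("subject_id", "dimension", "actual_mm", "predicted_mm")
  unmatched <- setdiff(run$results$subject_id, truth_long$subject_id)
  if (length(unmatched)) {
    rlang::warn(sprintf("subjects without actual measurements: %s",
                        paste(unmatched, collapse = ", ")))
    if (length(unmatched) > 0.1 * length(unique(run$results$subject_id))) {
      stop_validation("more than 10% of subjects lack actual measurements")
    }
  }
  report <- stratified_report(pairs, strata = character())
  out <- list(report = report, pairs = pairs,
              comparison = compare_distributions(pairs), run = run)
  if (!is.null(out_dir)) {
    write_run_outputs(run, out_dir)
    readr::write_csv(report$by_stratum,
                     file.path(out_dir, "error_report.csv"))
    readr::write_csv(out$comparison, file.path(out_dir, "comparison.csv"))
    ggplot2::ggsave(file.path(out_dir, "bland_altman.png"),
                    autoplot(bland_altman(pairs)),
                    width = 7, height = 5, dpi = 150)
  }
  out
}

#' Run the assigned-HVID sweep
#'
#' Orchestration wrapper around [sweep_assigned_hvid()]: generates the
#' configured synthetic population and sweeps the assigned value over the
#' configured grid. The `"oracle"` pipeline (default) uses ground-truth
#' measurements and unrendered scenes (the sweep is a property of the
#' calibration statistics); `"reference"` renders every scene and runs the
#' full classical pipeline.
#'
#' @inheritParams run_estimate
#' @return An `iriscal_sweep` object.
#' @export
run_sweep <- function(config = default_config(), out_dir = NULL) {
  if (config$input_mode != "synthetic") {
    stop_invalid("run_sweep requires synthetic input mode")
  }
  syn <- config$synthetic
  use_reference <- identical(config$sweep$pipeline, "reference")
  scenes <- sample_population(
    n = syn$n, hvid_mean = syn$hvid_mean, hvid_sd = syn$hvid_sd,
    magnification_range = syn$magnification_range,
    distance_ranges = syn$distance_ranges,
    occlusion_max = syn$occlusion_max, noise_sd = syn$noise_sd,
    seed = config$seed, render = use_reference)
  grid <- seq(config$sweep$grid_min, config$sweep$grid_max,
              by = config$sweep$grid_step)
  pipeline <- if (use_reference) config_measurer(config) else
    measure_scene_oracle
  sweep <- sweep_assigned_hvid(scenes, pipeline = pipeline, grid = grid,
                               combine = config$calibration$eye_combination)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(sweep$curve, file.path(out_dir, "sweep.csv"))
    ggplot2::ggsave(file.path(out_dir, "sweep.png"), autoplot(sweep),
                    width = 7, height = 5, dpi = 150)
  }
  sweep
}

#' Generate and export a synthetic study population
#'
#' @inheritParams run_estimate
#' @param directory Output directory for images, annotations and the
#'   pooled truth table.
#' @return Invisibly, the pooled truth CSV path.
#' @export
run_simulate <- function(config = default_config(), directory) {
  syn <- config$synthetic
  scenes <- sample_population(
    n = syn$n, hvid_mean = syn$hvid_mean, hvid_sd = syn$hvid_sd,
    magnification_range = syn$magnification_range,
    distance_ranges = syn$distance_ranges,
    occlusion_max = syn$occlusion_max, noise_sd = syn$noise_sd,
    seed = config$seed, render = TRUE)
  export_population(scenes, directory)
}
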