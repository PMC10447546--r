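# Statistical comparison of actual vs predicted measurements.
#
# Measurement pairs are rows of a tibble with `subject_id`, `dimension`
# ("horizontal"/"vertical"), `actual_mm`, `predicted_mm` and optional
# stratum columns (e.g. `sex`). Differences are taken as
# actual - predicted; SDs use the sample (n-1) denominator; MAPE is
# reported in percent.

check_pairs <- function(pairs, min_n = 1) {
  required <- c("actual_mm", "predicted_mm")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols)) {
    stop_validation(sprintf("pairs lack column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  if (nrow(pairs) < min_n) {
    stop_validation(sprintf("need at least %d measurement pair(s)", min_n))
  }
  bad <- which(pairs$actual_mm <= 0)
  if (length(bad)) {
    who <- if ("subject_id" %in% names(pairs)) {
      paste(pairs$subject_id[bad], collapse = ", ")
    } else paste(bad, collapse = ", ")
    stop_validation(sprintf(
      "actual_mm must be > 0 (MAPE denominator); offending subject(s): %s", who))
  }
  invisible(pairs)
}

#' Error metrics between actual and predicted measurements
#'
#' MAE = mean |A - P|, MSE = mean (A - P)^2, RMSE = sqrt(MSE) and
#' MAPE = 100 * mean |(A - P)/A| (percent).
#'
#' @param pairs Tibble with `actual_mm` and `predicted_mm` (one row per
#'   measurement).
#' @return One-row tibble `n`, `mae`, `mse`, `rmse`, `mape`.
#' @export
#' @examples
#' error_metrics(tibble::tibble(actual_mm = 100, predicted_mm = 98))
error_metrics <- function(pairs) {
  check_pairs(pairs, min_n = 1)
  d <- pairs$actual_mm - pairs$predicted_mm
  mse <- mean(d^2)
  tibble::tibble(
    n = nrow(pairs),
    mae = mean(abs(d)),
    mse = mse,
    rmse = sqrt(mse),
    mape = 100 * mean(abs(d / pairs$actual_mm))
  )
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = actual - predicted`; bias is their mean, and the limits
#' of agreement are bias +/- 1.96 times the sample SD of `d`.
#'
#' @param pairs Tibble with `actual_mm`, `predicted_mm` (n >= 2).
#' @return An `iriscal_bland_altman`: `stats` (one-row tibble `n`, `bias`,
#'   `sd_diff`, `loa_lower`, `loa_upper`) and `data` (per-pair `mean` and
#'   `diff`, for the agreement plot).
#' @export
bland_altman <- function(pairs) {
  check_pairs(pairs, min_n = 2)
  d <- pairs$actual_mm - pairs$predicted_mm
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(
      stats = tibble::tibble(n = length(d), bias = bias, sd_diff = s,
                             loa_lower = bias - 1.96 * s,
                             loa_upper = bias + 1.96 * s),
      data = tibble::tibble(mean = (pairs$actual_mm + pairs$predicted_mm) / 2,
                            diff = d)
    ),
    class = "iriscal_bland_altman"
  )
}

#' @export
print.iriscal_bland_altman <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<Bland-Altman: n = %d, bias = %.3f, LOA [%.3f, %.3f]>\n",
    s$n, s$bias, s$loa_lower, s$loa_upper))
  invisible(x)
}

#' @export
tidy.iriscal_bland_altman <- function(x, ...) x$stats

#' Stratified error report
#'
#' Mirrors the clinical reporting layout: per stratum and dimension the
#' mean +/- SD of the per-subject error terms (|A - P| for the MAE row,
#' (A - P)^2 for the MSE row, percent error for the MAPE row; the RMSE cell
#' is the square root of the stratum's mean squared error, with the SD of
#' the absolute error), plus a pooled Bland-Altman analysis per dimension.
#'
#' @param pairs Tibble with `subject_id`, `dimension`, `actual_mm`,
#'   `predicted_mm` and the stratum columns named in `strata`.
#' @param strata Character vector of stratum column names (may be empty for
#'   a pooled-only report).
#' @return An `iriscal_error_report`: `overall` (pooled metrics +
#'   Bland-Altman), `by_stratum`, `bland_altman_by_dimension`, and the
#'   input `pairs`.
#' @export
stratified_report <- function(pairs, strata = character()) {
  check_pairs(pairs, min_n = 1)
  if (!"dimension" %in% names(pairs)) pairs$dimension <- "all"
  missing_cols <- setdiff(strata, names(pairs))
  if (length(missing_cols)) {
    stop_validation(sprintf("stratum column(s) not present: %s",
                            paste(missing_cols, collapse = ", ")))
  }
  err <- dplyr::mutate(
    pairs,
    abs_err = abs(.data$actual_mm - .data$predicted_mm),
    sq_err = (.data$actual_mm - .data$predicted_mm)^2,
    pct_err = 100 * .data$abs_err / .data$actual_mm
  )

  summarise_cell <- function(df) {
    dplyr::summarise(
      df,
      n = dplyr::n(),
      mae_mean = mean(.data$abs_err), mae_sd = stats::sd(.data$abs_err),
      mse_mean = mean(.data$sq_err), mse_sd = stats::sd(.data$sq_err),
      rmse = sqrt(mean(.data$sq_err)),
      mape_mean = mean(.data$pct_err), mape_sd = stats::sd(.data$pct_err),
      .groups = "drop"
    )
  }

  by_stratum <- err |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(strata, "dimension")))) |>
    summarise_cell()

  ba_dim <- err |>
    dplyr::group_by(.data$dimension) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) return(tibble::tibble())
      bland_altman(df)$stats
    }) |>
    dplyr::ungroup()

  overall <- dplyr::bind_cols(
    error_metrics(pairs),
    if (nrow(pairs) >= 2) {
      dplyr::select(bland_altman(pairs)$stats, -"n")
    } else NULL
  )

  structure(list(overall = overall, by_stratum = by_stratum,
                 bland_altman_by_dimension = ba_dim, pairs = pairs),
            class = "iriscal_error_report")
}

#' @export
print.iriscal_error_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<error report: n = %d, MAE %.3f mm, RMSE %.3f mm, MAPE %.3f%%>\n",
    o$n, o$mae, o$rmse, o$mape))
  if (!is.null(o$bias)) {
    cat(sprintf("  Bland-Altman bias %.3f mm, LOA [%.3f, %.3f] mm\n",
                o$bias, o$loa_lower, o$loa_upper))
  }
  print(x$by_stratum)
  invisible(x)
}

#' @export
tidy.iriscal_error_report <- function(x, ...) x$by_stratum

#' @export
glance.iriscal_error_report <- function(x, ...) x$overall

#' Compare the distributions of actual and predicted measurements
#'
#' Per dimension: range, mean and SD of both series plus a paired two-sided
#' t-test p-value on the differences. Degenerate difference series (zero
#' variance) are flagged: p = 1 when all differences are zero, p = 0 for a
#' constant nonzero shift.
#'
#' @param pairs Tibble with `dimension`, `actual_mm`, `predicted_mm` (n >= 2
#'   per dimension).
#' @return Tibble, one row per dimension.
#' @export
compare_distributions <- function(pairs) {
  check_pairs(pairs, min_n = 2)
  if (!"dimension" %in% names(pairs)) pairs$dimension <- "all"
  pairs |>
    dplyr::group_by(.data$dimension) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) stop_validation("need n >= 2 per dimension")
      d <- df$actual_mm - df$predicted_mm
      p <- if (stats::sd(d) == 0) {
        if (all(d == 0)) 1 else 0
      } else {
        stats::t.test(df$actual_mm, df$predicted_mm, paired = TRUE)$p.value
      }
      tibble::tibble(
        n = nrow(df),
        actual_min = min(df$actual_mm), actual_max = max(df$actual_mm),
        actual_mean = mean(df$actual_mm), actual_sd = stats::sd(df$actual_mm),
        predicted_min = min(df$predicted_mm),
        predicted_max = max(df$predicted_mm),
        predicted_mean = mean(df$predicted_mm),
        predicted_sd = stats::sd(df$predicted_mm),
        degenerate = stats::sd(d) == 0,
        p_value = p
      )
    }) |>
    dplyr::ungroup()
}

#' Consistency validator for published error tables
#'
#' Checks each row of a stratified error table for the internal identity
#' RMSE^2 = MSE within the rounding tolerance implied by the printed
#' precision (both figures printed to 2 decimals: half an ulp of the MSE
#' plus the first-order propagation 2 * RMSE * 0.005 of the RMSE ulp).
#'
#' @param df Data frame with columns `rmse` and `mse` (mm and mm^2).
#' @param tolerance Optional fixed tolerance; by default computed per row
#'   as `0.01 * rmse + 0.005`.
#' @return The input with `implied_mse`, `discrepancy`, `tolerance` and
#'   `consistent` columns appended.
#' @export
validate_error_summary <- function(df, tolerance = NULL) {
  df |>
    dplyr::mutate(
      implied_mse = .data$rmse^2,
      discrepancy = abs(.data$implied_mse - .data$mse),
      tolerance = tolerance %||% (0.01 * .data$rmse + 0.005),
      consistent = .data$discrepancy <= .data$tolerance
    )
}
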