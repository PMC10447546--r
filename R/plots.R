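# ggplot2 autoplot methods for the result objects.

#' Bland-Altman agreement plot
#'
#' Mean of the paired values on x, their difference (actual - predicted)
#' on y, a solid line at the bias and dashed lines at the limits of
#' agreement.
#'
#' @param object An `iriscal_bland_altman`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iriscal_bland_altman <- function(object, ...) {
  s <- object$stats
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = s$bias, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(s$loa_lower, s$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of actual and predicted (mm)",
                  y = "Actual - predicted (mm)",
                  title = sprintf("Bland-Altman: bias %.2f mm, LOA [%.2f, %.2f]",
                                  s$bias, s$loa_lower, s$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Assigned-HVID sweep plot
#'
#' MAPE of the horizontal and vertical measurements as a function of the
#' assigned HVID, with the minimizing value marked.
#'
#' @param object An `iriscal_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iriscal_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve,
                              c("mape_horizontal", "mape_vertical"),
                              names_to = "dimension", values_to = "mape") |>
    dplyr::mutate(dimension = sub("mape_", "", .data$dimension))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$assigned_mm, y = .data$mape,
                                     colour = .data$dimension)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$argmin_mm, linetype = "dashed") +
    ggplot2::labs(x = "Assigned HVID (mm)", y = "MAPE (%)",
                  colour = "Measurement",
                  title = sprintf("Assigned-HVID sweep (argmin %.1f mm)",
                                  object$argmin_mm)) +
    ggplot2::theme_minimal()
}

#' Render a synthetic scene with its ground truth overlay
#'
#' @param scene A rendered `synthetic_scene`.
#' @param show_truth Overlay eye boxes and landmarks.
#' @return A ggplot.
#' @export
plot_scene <- function(scene, show_truth = TRUE) {
  if (is.null(scene$image)) stop_validation("scene was generated with render = FALSE")
  img <- scene$image
  df <- tibble::tibble(
    row = rep(seq_len(nrow(img)) - 1, times = ncol(img)),
    col = rep(seq_len(ncol(img)) - 1, each = nrow(img)),
    gray = as.vector(img)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (show_truth) {
    boxes <- dplyr::bind_rows(purrr::map(scene$eye_boxes, function(b) {
      tibble::tibble(row_min = b$row_min, col_min = b$col_min,
                     row_max = b$row_max, col_max = b$col_max)
    }))
    p <- p +
      ggplot2::geom_rect(data = boxes,
                         ggplot2::aes(xmin = .data$col_min, xmax = .data$col_max,
                                      ymin = .data$row_min, ymax = .data$row_max),
                         inherit.aes = FALSE,
                         colour = "red", fill = NA, linewidth = 0.5) +
      ggplot2::geom_point(data = scene$landmarks_px,
                          ggplot2::aes(x = .data$col, y = .data$row),
                          inherit.aes = FALSE, colour = "cyan", size = 1.5)
  }
  p
}
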