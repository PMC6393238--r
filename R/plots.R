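#' Plate heatmap
#'
#' Draws one or more 384-well plates as row-by-column heatmaps of a
#' chosen quantity (the Nluc/FFL ratio by default).
#'
#' @param wells Well tibble.
#' @param value One of `"ratio"`, `"ffl"`, `"nluc"`.
#' @return A ggplot object (facetted by plate).
#' @export
plot_plate <- function(wells, value = c("ratio", "ffl", "nluc")) {
  value <- match.arg(value)
  wells <- dplyr::mutate(
    wells,
    ratio = suppressWarnings(well_ratio(.data$nluc, .data$ffl)),
    row_f = factor(.data$row, levels = rev(plate_rows)))
  ggplot2::ggplot(wells, ggplot2::aes(x = .data$column, y = .data$row_f,
                                      fill = .data[[value]])) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::scale_x_continuous(breaks = c(1, 6, 12, 18, 23, 24)) +
    ggplot2::facet_wrap(~plate_id) +
    ggplot2::labs(x = "column", y = "row", fill = value) +
    ggplot2::theme_minimal()
}

#' @describeIn analyze_screen Scatter of percent inhibition by plate with
#'   the hit and activator thresholds marked, after removal of toxic
#'   compounds (the campaign-overview plot).
#' @param object A `screen_result`.
#' @export
autoplot.screen_result <- function(object, ...) {
  r <- dplyr::filter(object$results, !.data$excluded, !.data$toxic_flag)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$plate_id,
                                  y = .data$pct_inhibition)) +
    ggplot2::geom_jitter(width = 0.25, size = 0.4, alpha = 0.4,
                         ggplot2::aes(color = .data$hit_flag |
                                        .data$activator_flag)) +
    ggplot2::geom_hline(yintercept = object$thresholds$hit_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$thresholds$activator_threshold,
                        linetype = "dotted") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "red"),
                                guide = "none") +
    ggplot2::labs(x = "plate", y = "% inhibition (Nluc/FFL ratio)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 6))
}

#' @describeIn fit_4pl Dose-response points and fitted curve on a log
#'   dose axis.
#' @param object A `dose_response_fit`.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose,
                                                 y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (uM)", y = "% inhibition") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- exp(seq(log(min(object$data$dose)), log(max(object$data$dose)),
                    length.out = 200))
    curve <- object$bottom + (object$top - object$bottom) /
      (1 + (object$ic50 / grid)^object$hill)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(dose = grid, response = curve),
      color = "steelblue") +
      ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed")
  }
  p
}
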