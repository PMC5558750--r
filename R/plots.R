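# ggplot2 views of the main result types.

#' Plot a class series with an optional forecast fan
#'
#' @param series A `sccpay_class_series` (or any tibble with `year`, `month`,
#'   `value`).
#' @param forecast Optional forecast tibble from [forecast_sarima()].
#' @return A ggplot.
#' @export
plot_class_series <- function(series, forecast = NULL) {
  series <- dplyr::mutate(series, t = month_index(.data$year, .data$month))
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "month", y = "BTSCC (cells/mL)",
      title = if ("class_index" %in% names(series)) {
        sprintf("Class %d monthly BTSCC", series$class_index[1])
      } else {
        "Monthly BTSCC"
      }
    ) +
    ggplot2::theme_minimal()
  if (!is.null(forecast)) {
    fc <- dplyr::mutate(forecast, t = max(series$t) + .data$h)
    p <- p +
      ggplot2::geom_ribbon(
        data = fc,
        ggplot2::aes(x = .data$t, ymin = .data$lower, ymax = .data$upper),
        inherit.aes = FALSE, alpha = 0.25
      ) +
      ggplot2::geom_line(
        data = fc, ggplot2::aes(x = .data$t, y = .data$point),
        inherit.aes = FALSE, linetype = "dashed"
      )
  }
  p
}

#' Heatmap of quadrant class-change probabilities
#'
#' @param cells Quadrant tibble from [empirical_change_probabilities()].
#' @return A ggplot faceted by payment class.
#' @export
plot_quadrants <- function(cells) {
  ggplot2::ggplot(
    cells,
    ggplot2::aes(x = factor(.data$mean_bin), y = factor(.data$sd_bin),
                 fill = .data$probability)
  ) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~class_index, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "mean bin (50,000 cells/mL steps)",
                  y = "SD bin (50,000 cells/mL steps)",
                  fill = "% change\nto worse") +
    ggplot2::theme_minimal()
}

#' Regression diagnostic panels for a class-change model
#'
#' Standardized residuals against fitted values and a normal Q-Q plot — the
#' graphical assumption checks for the quadrant regression.
#'
#' @param model A `class_change_model`.
#' @return A ggplot (two facets).
#' @export
plot_change_model_diagnostics <- function(model) {
  d <- change_model_diagnostics(model)$series
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "residuals vs fitted", x = d$fitted,
                   y = d$std_residual),
    tibble::tibble(panel = "normal Q-Q", x = d$theoretical,
                   y = d$std_residual)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "standardized residual") +
    ggplot2::theme_minimal()
}

#' Bar chart of annual losses as a share of daily production
#'
#' @param losses A `loss_table`.
#' @param profit_margin Profit margin fraction (default 0.15).
#' @return A ggplot.
#' @export
plot_loss_pct <- function(losses, profit_margin = 0.15) {
  d <- dplyr::mutate(
    losses$annual,
    pct = liters_per_day_pct(.data$annual_loss, profit_margin)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$class_index),
                                  y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "payment class", y = "% of daily production") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.loss_table <- function(object, ...) plot_loss_pct(object, ...)

#' @export
autoplot.sccpay_class_series <- function(object, ...) {
  plot_class_series(object, ...)
}
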