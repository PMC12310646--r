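#' Plot an annual reporting trend
#'
#' Bars of case counts per reporting year, annotated with the Spearman
#' correlation computed by [annual_trend()].
#'
#' @param object A `trend_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.trend_result <- function(object, ...) {
  cc <- attr(object, "correlation")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year,
                                       y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Reporting year", y = "Cases",
      subtitle = sprintf("Spearman r = %.4f, p = %.2g",
                         cc$r, cc$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a time-to-onset histogram
#'
#' @param object A `tto_summary`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tto_summary <- function(object, ...) {
  hist <- attr(object, "histogram")
  pooled <- object[object$drug == "all", ]
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_vline(xintercept = pooled$median_days,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Days from drug start to onset", y = "Cases",
                  subtitle = sprintf(
                    "median %.0f d (IQR %.0f-%.0f), n = %d",
                    pooled$median_days, pooled$q1_days,
                    pooled$q3_days, pooled$n_usable)) +
    ggplot2::theme_minimal()
}

#' Mortality-rate bar chart per event group
#'
#' @param data Output of [mortality_rates()].
#' @return A ggplot object.
#' @export
plot_mortality <- function(data) {
  ggplot2::ggplot(data,
                  ggplot2::aes(x = stats::reorder(.data$group,
                                                  .data$rate_pct),
                               y = .data$rate_pct)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mortality rate (%)") +
    ggplot2::theme_minimal()
}

#' Forest plot of reporting odds ratios
#'
#' @param data Tibble with columns `drug` (or `event`), `ror`, `ror_lo`,
#'   `ror_hi`, e.g. from [signal_stats()].
#' @param label Column to use for the y axis.
#' @return A ggplot object.
#' @export
plot_signal_forest <- function(data, label = "drug") {
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data$ror,
                               y = stats::reorder(.data[[label]],
                                                  .data$ror))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror_lo,
                                         xmax = .data$ror_hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ROR (log scale, 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
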