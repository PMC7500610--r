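# Diagnostic plots for fitted objects and results.

#' Partial dependence plot
#'
#' @param pd a [partial_dependence()] tibble.
#' @param variable axis label.
#' @return A ggplot.
#' @export
plot_partial_dependence <- function(pd, variable = "predictor") {
  ggplot2::ggplot(pd, ggplot2::aes(.data$value, .data$yhat)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = variable, y = "mean predicted yield (kg/ha)") +
    ggplot2::theme_minimal()
}

#' Robustness CDF plot
#'
#' Cumulative distribution of BK-over-ZERO net revenue gains under each
#' response scaling factor.
#'
#' @param object a [robustness_cdf()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.robustness_cdf <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(.data$threshold, .data$cdf,
                               colour = factor(.data$s))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gain, BK over ZERO (USD/ha)",
                  y = "cumulative share of maize area",
                  colour = "response\nscaling s") +
    ggplot2::theme_minimal()
}

#' Scenario comparison plot
#'
#' Maize-area-weighted mean N rate, yield and net revenue per scenario.
#'
#' @param scenarios named list of `scenario_result`s.
#' @param maize_area optional weight raster.
#' @return A ggplot.
#' @export
plot_scenarios <- function(scenarios, maize_area = NULL) {
  df <- purrr::imap_dfr(scenarios, function(res, nm) {
    tibble::tibble(
      scenario = nm,
      quantity = c("N rate (kg/ha)", "yield (kg/ha)", "net revenue (USD/ha)"),
      value = c(gr_mean(res$n_rate, maize_area),
                gr_mean(res$yield, maize_area),
                gr_mean(res$netrev, maize_area))
    )
  })
  df$scenario <- factor(df$scenario, levels = names(scenarios))
  ggplot2::ggplot(df, ggplot2::aes(.data$scenario, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
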