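#' Cost-effectiveness plane
#'
#' Scatter of the bootstrapped incremental draws, incremental effect on
#' the horizontal axis and incremental cost (EUR) on the vertical axis.
#' Draws in the south-east (dominant) quadrant are more effective at a
#' lower cost.
#'
#' @param draws a `cea_draws` data frame.
#' @param measure `"remission"` or `"qaly"`.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, measure = "remission") {
  de <- draws[[.measure_col(measure)]]
  df <- data.frame(delta_effect = de, delta_cost = draws$delta_cost)
  xlab <- switch(measure,
                 remission = "Incremental remission increase",
                 qaly = "Incremental QALYs")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_effect,
                                   y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = xlab, y = "Incremental cost (EUR)") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac_df a `cea_ceac` data frame, or a long data frame with an
#'   extra `scenario` column (one curve per scenario).
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  p <- if ("scenario" %in% names(ceac_df)) {
    ggplot2::ggplot(ceac_df, ggplot2::aes(x = .data$wtp,
                                          y = .data$probability,
                                          colour = .data$scenario))
  } else {
    ggplot2::ggplot(ceac_df, ggplot2::aes(x = .data$wtp,
                                          y = .data$probability))
  }
  p + ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR per effect unit)",
                  y = "P(cost-effective)") +
    ggplot2::theme_minimal()
}
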