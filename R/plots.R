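#' Forest plot of pooled stratified odds ratios
#'
#' Plots the pooled OR and 95% CI per stratum level, faceted by outcome and
#' stratification variable, coloured by heat-wave definition — the layout of
#' a stratified-analysis forest plot.
#'
#' @param object A `"heatbirth_results"` object from [run_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.heatbirth_results <- function(object, ...) {
  tab <- summarize_results(object)
  ggplot2::ggplot(
    tab,
    ggplot2::aes(x = .data$or, y = .data$stratum_level,
                 xmin = .data$lcl, xmax = .data$ucl,
                 colour = .data$hw_def)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_grid(stratum_var ~ outcome, scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL,
                  colour = "Heat-wave definition") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.heatbirth_results
#' @param results A `"heatbirth_results"` object.
#' @export
plot_forest <- function(results) {
  autoplot.heatbirth_results(results)
}
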