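#' Histogram of a risk distribution
#'
#' Distribution of an absolute-risk measure across the cohort, optionally
#' faceted by a grouping column (e.g. sex).
#'
#' @param scores a `risk_score_set`.
#' @param measure column to plot, `"risk_lifetime"` or `"risk_10y"`.
#' @param bins number of histogram bins.
#' @return A ggplot object.
#' @export
plot_risk_distribution <- function(scores, measure = "risk_lifetime",
                                   bins = 60) {
  if (!measure %in% names(scores)) stop("no column '", measure, "' in scores")
  ggplot2::ggplot(as.data.frame(scores),
                  ggplot2::aes(x = .data[[measure]])) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white",
                            linewidth = 0.1) +
    ggplot2::labs(x = paste("absolute", gsub("risk_", "", measure), "risk"),
                  y = "participants") +
    ggplot2::theme_minimal()
}

#' Forest-style comparison of stratified SIRs
#'
#' Point estimates with confidence intervals for a set of strata, e.g.
#' family-history categories against risk quantiles.
#'
#' @param sir_df data frame from [sir_table()] (columns `label`, `sir`,
#'   `ci_low`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_sir_comparison <- function(sir_df) {
  sir_df$label <- factor(sir_df$label, levels = sir_df$label)
  ggplot2::ggplot(sir_df, ggplot2::aes(x = .data$label, y = .data$sir)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey55") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "standardised incidence ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
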