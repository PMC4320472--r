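#' Plot an accuracy report
#'
#' Bar chart of mean accuracy by method (empirical, selection index,
#' population parameters) with error bars of one standard error where a
#' spread axis exists, per candidate population.
#'
#' @param object An [run_scenario()] accuracy report or a list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accuracy_report
#' @export
autoplot.accuracy_report <- function(object, ...) {
  tab <- summarize_replicates(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$scenario, y = .data$mean,
                                    fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2,
      na.rm = TRUE) +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "scenario", y = "accuracy of genomic prediction",
                  fill = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Cross-population allele-frequency comparison
#'
#' Scatter of per-locus allele frequencies between two populations of a
#' panel, annotated with their correlation — the panel-level signature of
#' breed divergence.
#'
#' @param panel A [genotype_panel()].
#' @param pop_a,pop_b Population labels.
#' @return A ggplot object.
#' @export
plot_allele_frequencies <- function(panel, pop_a, pop_b) {
  af <- allele_frequencies(panel)
  tab <- tibble::tibble(a = af$per_population[pop_a, ],
                        b = af$per_population[pop_b, ])
  r <- stats::cor(tab$a, tab$b)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(
      x = paste("allele frequency,", pop_a),
      y = paste("allele frequency,", pop_b),
      subtitle = sprintf("correlation = %.2f", r)) +
    ggplot2::theme_minimal()
}
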