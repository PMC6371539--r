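# ggplot2 views of cohorts and estimate tables.

#' Sib-pair scatterplot with the least-squares fit
#'
#' @param pairs A `pair_cohort` or a [pair_table()] tibble.
#' @return A ggplot: member-2 vs member-1 phenotype points with the fitted
#'   regression line. Under a pure XOR architecture the cloud is visibly
#'   multimodal; under the additive and combined models it is a single tilted
#'   ellipse.
#' @export
plot_pair_scatter <- function(pairs) {
  if (inherits(pairs, "pair_cohort")) pairs <- pair_table(pairs)
  ggplot2::ggplot(pairs, ggplot2::aes(.data$member1_phenotype,
                                      .data$member2_phenotype)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "member 1 phenotype", y = "member 2 phenotype") +
    ggplot2::theme_minimal()
}

#' Correlation versus relatedness
#'
#' @param triples A tibble with columns `relatedness` and `correlation`
#'   (optionally `preset` for faceting), e.g. panels d-f of
#'   [reproduce_figure1()] or rows of `run_experiment()$estimates`.
#' @return A ggplot of the correlation points against expected relatedness
#'   with a through-the-origin reference line per group — the linearity
#'   diagnostic that distinguishes additive from purely epistatic traits.
#' @export
plot_correlation_vs_relatedness <- function(triples) {
  p <- ggplot2::ggplot(triples, ggplot2::aes(.data$relatedness,
                                             .data$correlation)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ 0 + x, se = FALSE,
                         linewidth = 0.5, linetype = 2) +
    ggplot2::expand_limits(x = 0, y = 0) +
    ggplot2::labs(x = "expected relatedness", y = "pair correlation") +
    ggplot2::theme_minimal()
  if ("preset" %in% names(triples)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$preset))
  }
  p
}

#' @rdname plot_pair_scatter
#' @param object A `pair_cohort`.
#' @param ... Unused.
#' @method autoplot pair_cohort
#' @export
autoplot.pair_cohort <- function(object, ...) plot_pair_scatter(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
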