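#' Plot sibling-recurrence odds ratios
#'
#' Odds ratios with 95% Wald intervals per outcome, colored by index-case
#' sex and faceted by index diagnosis group, on a log scale with the null
#' OR = 1 marked.
#'
#' @param results Tibble from [run_recurrence_analysis()].
#' @return A ggplot object.
#' @export
plot_recurrence <- function(results) {
  ggplot2::ggplot(
    dplyr::filter(results, is.finite(.data$odds_ratio)),
    ggplot2::aes(x = .data$outcome, y = .data$odds_ratio,
                 colour = .data$index_sex)
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(
      values = c(female = "#c0392b", male = "#16a085"),
      name = "index case sex"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$index_group)) +
    ggplot2::labs(
      x = "sibling outcome",
      y = "odds ratio vs matched controls (log scale)",
      title = "Sibling recurrence by index-case sex"
    ) +
    ggplot2::theme_minimal()
}

#' Plot pTDT deviations by stratum
#'
#' Mean standardized polygenic transmission deviations with 95% confidence
#' intervals, against the Mendelian null of zero.
#'
#' @param results Tibble from [run_ptdt()].
#' @return A ggplot object.
#' @export
plot_ptdt <- function(results) {
  ggplot2::ggplot(
    results,
    ggplot2::aes(x = .data$stratum, y = .data$mean_deviation)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_deviation - 1.96 * .data$standard_error,
      ymax = .data$mean_deviation + 1.96 * .data$standard_error
    )) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL,
      y = "polygenic deviation from mid-parent (mid-parent SD)",
      title = "Polygenic transmission disequilibrium by stratum"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for scenario runs
#'
#' @param object An `fpe_scenario` from [run_fpe_scenario()].
#' @param which `"recurrence"` or `"ptdt"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fpe_scenario <- function(object, which = c("recurrence", "ptdt"), ...) {
  which <- match.arg(which)
  if (which == "recurrence") plot_recurrence(object$recurrence)
  else plot_ptdt(object$ptdt)
}
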