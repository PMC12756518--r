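#' Funnel plot of site rates with exact binomial control limits
#'
#' Scatter of site outcome rates against case volume, with the benchmark
#' line and the 95% (by default) exact binomial control-limit curves.
#' Sites above the upper limit are the flagged underperformance outliers;
#' excluded sites (case volume below the minimum) are drawn hollow.
#'
#' @param summaries Site summaries (after [apply_case_volume_minimum()] if
#'   a case-volume minimum applies).
#' @param estimate Which site estimate to plot: `"unadjusted"` or
#'   `"adjusted"`.
#' @param benchmark Benchmark proportion; defaults to the pooled event
#'   proportion over included sites.
#' @param level Control-limit level.
#' @return A ggplot object.
#' @export
plot_funnel <- function(summaries, estimate = c("unadjusted", "adjusted"),
                        benchmark = NULL, level = 0.95) {
  estimate <- match.arg(estimate)
  incl <- summaries$included
  benchmark <- benchmark %||%
    (sum(summaries$observed[incl]) / sum(summaries$n_patients[incl]))
  rate <- if (estimate == "unadjusted") {
    summaries$unadjusted_rate
  } else {
    summaries$observed / summaries$expected * benchmark
  }
  pts <- tibble::tibble(
    n = summaries$n_patients, rate = rate,
    included = factor(ifelse(incl, "included", "excluded"),
                      levels = c("included", "excluded"))
  )
  n_grid <- unique(pmax(1L, round(exp(seq(log(max(1, min(pts$n))),
                                          log(max(pts$n)), length.out = 120)))))
  lims <- funnel_limits(n_grid, benchmark, level)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$n, y = .data$rate)) +
    ggplot2::geom_line(
      data = lims, inherit.aes = FALSE, linetype = "dashed",
      colour = "firebrick",
      mapping = ggplot2::aes(x = .data$n, y = .data$upper_rate)
    ) +
    ggplot2::geom_line(
      data = lims, inherit.aes = FALSE, linetype = "dashed",
      colour = "steelblue",
      mapping = ggplot2::aes(x = .data$n, y = .data$lower_rate)
    ) +
    ggplot2::geom_hline(yintercept = benchmark, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$included), size = 2) +
    ggplot2::scale_shape_manual(values = c(included = 16, excluded = 1),
                                drop = FALSE) +
    ggplot2::labs(
      x = "Case volume (patients)",
      y = sprintf("%s site rate",
                  if (estimate == "unadjusted") "Unadjusted" else "Risk-adjusted"),
      shape = NULL,
      title = sprintf("Funnel plot (%s estimates, %.0f%% exact binomial limits)",
                      estimate, 100 * level)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a metric across a parameter sweep
#'
#' Line plot of an aggregated metric (default ROC AUC) against a swept
#' scenario parameter, one line per method combination, faceted by
#' prevalence — the standard way to read a registry-size sweep.
#'
#' @param summary_tbl A [grid_summary()] tibble.
#' @param x Name of the x-axis column (e.g. `"n_sites"`,
#'   `"patients_per_site"`, `"case_volume_minimum"`).
#' @param metric Metric to plot.
#' @return A ggplot object.
#' @export
plot_sweep <- function(summary_tbl, x, metric = "roc_auc") {
  tab <- summary_tbl[summary_tbl$metric == metric, ]
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data[[x]], y = .data$mean,
    colour = .data$combination, group = .data$combination
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0
    ) +
    ggplot2::facet_wrap(~prevalence, labeller = ggplot2::label_both) +
    ggplot2::labs(x = x, y = metric, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
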