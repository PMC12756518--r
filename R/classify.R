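#' Apply a case-volume minimum to site summaries
#'
#' Sites whose case volume falls below the minimum are excluded from
#' benchmarking: they can never be flagged, and are counted as (unflagged)
#' negatives when classification accuracy is scored.
#'
#' @param summaries A [summarize_sites()] tibble.
#' @param minimum Nonnegative patient-count threshold.
#' @return The summaries with `included` set to `n_patients >= minimum`.
#' @export
apply_case_volume_minimum <- function(summaries, minimum) {
  stopifnot(minimum >= 0)
  summaries$included <- summaries$n_patients >= minimum
  summaries
}

#' Exact binomial upper control limit (flagging threshold on events)
#'
#' For a funnel plot around benchmark rate `p0` at case volume `n`, the
#' upper control limit is the smallest event count \eqn{k^*} whose upper
#' tail probability under Binomial(`n`, `p0`) is at most half the
#' complement of `level` (2.5% for 95% limits): a site is flagged as an
#' underperformance outlier when its events reach \eqn{k^*}. The threshold
#' can equal `n + 1`, meaning no attainable event count flags a site of
#' that volume.
#'
#' @param n Case volume(s), each at least 1.
#' @param p0 Benchmark proportion(s) in (0, 1).
#' @param level Two-sided coverage level (default 0.95).
#' @return Integer vector of thresholds, same length as `n`.
#' @examples
#' exact_binomial_upper_limit(100, 0.05)
#' @export
exact_binomial_upper_limit <- function(n, p0, level = 0.95) {
  stopifnot(all(n >= 1), all(p0 > 0), all(p0 < 1), level > 0, level < 1)
  alpha <- (1 - level) / 2
  tail_ok <- function(k, n1, p1) {
    # P(X >= k) <= alpha; P(X >= 0) = 1 so k* >= 1 always
    pbinom(k - 1, n1, p1, lower.tail = FALSE) <= alpha
  }
  out <- mapply(function(n1, p1) {
    k <- qbinom(1 - alpha, n1, p1) + 1L
    while (k <= n1 && !tail_ok(k, n1, p1)) k <- k + 1L
    while (k > 1L && tail_ok(k - 1L, n1, p1)) k <- k - 1L
    k
  }, as.integer(n), p0)
  as.integer(out)
}

#' Exact binomial lower control limit
#'
#' Companion of [exact_binomial_upper_limit()] for drawing the lower arm of
#' a funnel plot: the largest event count whose lower tail probability is
#' at most half the complement of `level`, or -1 when even zero events are
#' not that extreme. Low-side deviations are never flagged as outliers
#' (outliers are defined as underperformers); the limit is provided for
#' visualisation.
#'
#' @inheritParams exact_binomial_upper_limit
#' @return Integer vector of thresholds (possibly -1).
#' @export
exact_binomial_lower_limit <- function(n, p0, level = 0.95) {
  stopifnot(all(n >= 1), all(p0 > 0), all(p0 < 1), level > 0, level < 1)
  alpha <- (1 - level) / 2
  out <- mapply(function(n1, p1) {
    k <- qbinom(alpha, n1, p1) + 1L
    while (k >= 0L && pbinom(k, n1, p1) > alpha) k <- k - 1L
    k
  }, as.integer(n), p0)
  as.integer(out)
}

#' Byar approximation to the lower exact Poisson confidence bound
#'
#' Closed-form approximation to the lower limit of an exact two-sided
#' Poisson confidence interval for a mean, given an observed event count
#' \eqn{O}: \eqn{L = O (1 - 1/(9O) - z/(3\sqrt{O}))^3}, floored at zero,
#' with \eqn{z} the standard-normal quantile at \eqn{1-(1-level)/2}. Zero
#' events give a zero bound. Standard practice for standardised ratios of
#' observed to expected events, treating the count as Poisson.
#'
#' @param O Observed event count(s), nonnegative.
#' @param level Two-sided coverage level (default 0.95).
#' @return Numeric vector of lower bounds.
#' @examples
#' byar_lower_bound(10)
#' qgamma(0.025, 10)  # exact Poisson counterpart
#' @export
byar_lower_bound <- function(O, level = 0.95) {
  stopifnot(all(O >= 0), level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  out <- numeric(length(O))
  pos <- O > 0
  Op <- O[pos]
  out[pos] <- pmax(0, Op * (1 - 1 / (9 * Op) - z / (3 * sqrt(Op)))^3)
  out
}

#' Confidence-interval outlier flags for one set of site summaries
#'
#' A site is flagged when the lower bound of the (Byar-approximated)
#' confidence interval for its rate lies above the benchmark: for
#' unadjusted estimates when \eqn{L(O_j)/n_j > \bar p}, and for adjusted
#' estimates when \eqn{L(O_j)/E_j > 1} (equivalently, the lower bound of
#' the indirectly standardised rate exceeds the benchmark).
#'
#' @param summaries Site summaries with `included` set.
#' @param benchmark The benchmark proportion \eqn{\bar p}.
#' @param level Two-sided coverage level.
#' @return A tibble with logical columns `unadjusted` and `adjusted`
#'   (`NA` where the adjusted estimate is unavailable); excluded sites are
#'   `FALSE`.
#' @export
flag_confidence_interval <- function(summaries, benchmark, level = 0.95) {
  lower <- byar_lower_bound(summaries$observed, level)
  unadj <- lower / summaries$n_patients > benchmark
  adj <- ifelse(is.na(summaries$expected), NA,
                summaries$expected > 0 & lower / summaries$expected > 1)
  unadj[!summaries$included] <- FALSE
  adj[!summaries$included] <- FALSE
  tibble::tibble(unadjusted = unadj, adjusted = as.logical(adj))
}

#' Control-limit outlier flags for one set of site summaries
#'
#' Flags a site when its event count reaches the exact binomial upper
#' control limit computed at its case volume and the benchmark rate. For
#' adjusted estimates the indirectly standardised rate is placed on the
#' funnel at the site's case volume, i.e. the flag compares
#' `adjusted_rate * n_j` to the same threshold.
#'
#' @inheritParams flag_confidence_interval
#' @return A tibble with logical columns `unadjusted` and `adjusted`.
#' @export
flag_control_limits <- function(summaries, benchmark, level = 0.95) {
  incl <- summaries$included
  kstar <- rep(NA_integer_, nrow(summaries))
  ok <- incl & summaries$n_patients >= 1
  kstar[ok] <- exact_binomial_upper_limit(summaries$n_patients[ok],
                                          benchmark, level)
  unadj <- summaries$observed >= kstar
  adj_rate <- summaries$adjusted_rate
  # re-standardise to the benchmark over included sites
  adj_events <- ifelse(is.na(summaries$expected), NA_real_,
                       summaries$observed / summaries$expected *
                         benchmark * summaries$n_patients)
  adj <- adj_events >= kstar
  unadj[!incl] <- FALSE
  adj[!incl] <- FALSE
  tibble::tibble(unadjusted = unadj, adjusted = adj)
}

#' Classify outlier sites under all four method combinations
#'
#' Evaluates the two site estimates (unadjusted, risk-adjusted) crossed
#' with the two classification techniques (95% exact binomial control
#' limits, 95% Byar-approximation confidence intervals) on one set of site
#' summaries. The benchmark is the pooled patient-level event proportion
#' over included sites; excluded sites carry `FALSE` in all four flags.
#'
#' @param summaries Site summaries after [apply_case_volume_minimum()].
#' @param level Two-sided level for both techniques (default 0.95).
#' @return A tibble of class `flag_set`: `site_id`, `included`, and logical
#'   columns `unadjusted_control_limits`, `adjusted_control_limits`,
#'   `unadjusted_confidence_interval`, `adjusted_confidence_interval`
#'   (adjusted columns are `NA` when the risk model did not converge). The
#'   benchmark used is attached as attribute `"benchmark"`.
#' @export
classify <- function(summaries, level = 0.95) {
  incl <- summaries$included
  n_incl <- sum(summaries$n_patients[incl])
  benchmark <- if (n_incl > 0) {
    sum(summaries$observed[incl]) / n_incl
  } else {
    NA_real_
  }
  falses <- rep(FALSE, nrow(summaries))
  if (!is.finite(benchmark) || benchmark <= 0 || benchmark >= 1) {
    # degenerate benchmark (no included sites, or 0%/100% pooled rate):
    # no site can be distinguished from it
    out <- tibble::tibble(
      site_id = summaries$site_id, included = incl,
      unadjusted_control_limits = falses,
      adjusted_control_limits = falses,
      unadjusted_confidence_interval = falses,
      adjusted_confidence_interval = falses
    )
  } else {
    cl <- flag_control_limits(summaries, benchmark, level)
    ci <- flag_confidence_interval(summaries, benchmark, level)
    out <- tibble::tibble(
      site_id = summaries$site_id, included = incl,
      unadjusted_control_limits = cl$unadjusted,
      adjusted_control_limits = cl$adjusted,
      unadjusted_confidence_interval = ci$unadjusted,
      adjusted_confidence_interval = ci$adjusted
    )
  }
  attr(out, "benchmark") <- benchmark
  class(out) <- c("flag_set", class(out))
  out
}

#' Funnel-plot control-limit curves
#'
#' Exact binomial control limits on the proportion scale over a range of
#' case volumes, for drawing or exporting funnel plots: `upper_rate` is the
#' smallest flaggable rate at each volume and `lower_rate` the largest
#' low-side-extreme rate (never flagged, shown for symmetry).
#'
#' @param n Vector of case volumes.
#' @param p0 Benchmark proportion.
#' @param level Two-sided coverage level.
#' @return A tibble with `n`, `lower_rate`, `upper_rate`.
#' @export
funnel_limits <- function(n, p0, level = 0.95) {
  upper <- exact_binomial_upper_limit(n, p0, level)
  lower <- exact_binomial_lower_limit(n, p0, level)
  tibble::tibble(
    n = as.integer(n),
    lower_rate = pmax(lower, 0L) / n,
    upper_rate = pmin(upper, n) / n
  )
}
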