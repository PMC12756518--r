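#' Confusion counts for one flag vector against true outlier status
#'
#' @param flags Logical flags (excluded sites must carry `FALSE`). Any `NA`
#'   (e.g. adjusted methods on a replicate whose risk model failed) makes
#'   all four counts `NA` — the combination is undefined for the replicate.
#' @param truth Logical true-outlier status, same length.
#' @return Named integer vector `c(tp, fp, tn, fn)`, conserving the site
#'   count.
#' @export
confusion <- function(flags, truth) {
  stopifnot(length(flags) == length(truth), !anyNA(truth))
  if (anyNA(flags)) {
    return(c(tp = NA_integer_, fp = NA_integer_,
             tn = NA_integer_, fn = NA_integer_))
  }
  flags <- as.logical(flags)
  truth <- as.logical(truth)
  c(
    tp = sum(flags & truth),
    fp = sum(flags & !truth),
    tn = sum(!flags & !truth),
    fn = sum(!flags & truth)
  )
}

#' Classification accuracy metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive and negative
#' predictive values, and the binary-classifier ROC AUC
#' (sensitivity + specificity)/2 — the area under the two-point ROC curve,
#' the only AUC available from hard classifications. Metrics whose
#' denominator is zero (e.g. sensitivity in a replicate with no true
#' outliers, PPV when nothing is flagged) are `NA`, never zero by
#' convention; the ROC AUC is `NA` whenever sensitivity is.
#'
#' @param conf Named counts from [confusion()].
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `roc_auc`.
#' @export
replicate_metrics <- function(conf) {
  rate <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  tp <- conf[["tp"]]; fp <- conf[["fp"]]; tn <- conf[["tn"]]; fn <- conf[["fn"]]
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens,
    specificity = spec,
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    roc_auc = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  )
}

#' Aggregate per-replicate metrics with normal-approximation 95% CIs
#'
#' Averages each metric over the replicates where it is defined and
#' attaches `mean +/- 1.96 sd/sqrt(n_defined)` confidence intervals.
#' Replicates where a metric is undefined (no true outliers, failed risk
#' model, nothing flagged) simply do not contribute to that metric;
#' `n_defined` records how many did. A mean needs at least one defined
#' replicate and a CI at least two; below two a warning is raised.
#'
#' @param per_replicate Tibble with columns `replicate`, `combination` and
#'   the [replicate_metrics()] columns.
#' @return A tidy tibble: `combination`, `metric`, `mean`, `ci_low`,
#'   `ci_high`, `n_defined`.
#' @export
aggregate_metrics <- function(per_replicate) {
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "roc_auc")
  long <- metric_long(per_replicate, metrics)
  out <- long |>
    dplyr::group_by(.data$combination, .data$metric) |>
    dplyr::summarise(
      n_defined = sum(!is.na(.data$value)),
      mean = ifelse(n_defined >= 1, mean(.data$value, na.rm = TRUE), NA_real_),
      se = ifelse(n_defined >= 2,
                  sd(.data$value, na.rm = TRUE) / sqrt(n_defined), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_low = .data$mean - 1.96 * .data$se,
      ci_high = .data$mean + 1.96 * .data$se
    ) |>
    dplyr::select(dplyr::all_of(c("combination", "metric", "mean",
                                  "ci_low", "ci_high", "n_defined")))
  if (any(out$n_defined < 2)) {
    warning("some metrics had fewer than 2 defined replicates; ",
            "their CIs (and, with none defined, their means) are NA")
  }
  out
}

# minimal long-format reshape (avoids a tidyr dependency for one verb)
metric_long <- function(df, cols) {
  parts <- lapply(cols, function(m) {
    tibble::tibble(combination = df$combination, metric = m, value = df[[m]])
  })
  dplyr::bind_rows(parts)
}

#' Pooled-count metrics across replicates
#'
#' Alternative aggregation that sums the confusion counts over replicates
#' per method combination and computes one set of metrics from the pooled
#' table. Unlike per-replicate averaging it needs no policy for replicates
#' with undefined metrics (a replicate with no true outliers still
#' contributes its negatives).
#'
#' @param per_replicate As for [aggregate_metrics()].
#' @return A tibble: `combination` plus the pooled [replicate_metrics()]
#'   columns.
#' @export
pooled_metrics <- function(per_replicate) {
  ok <- per_replicate[!is.na(per_replicate$tp), ]
  parts <- lapply(split(ok, ok$combination), function(d) {
    m <- replicate_metrics(c(tp = sum(d$tp), fp = sum(d$fp),
                             tn = sum(d$tn), fn = sum(d$fn)))
    tibble::tibble(combination = d$combination[1], m)
  })
  dplyr::bind_rows(parts)
}

#' Average patients per site needed for a target event count
#'
#' Planning arithmetic: with outcome prevalence \eqn{p}, reaching an
#' average of `event_threshold` observed events per site requires
#' `event_threshold / p` patients per site (rounded to the nearest whole
#' patient). A threshold of 100 events corresponds to 2000 patients per
#' site at 5% prevalence, 250 at 40% and 111 at 90%.
#'
#' @param event_threshold Target events per site (>= 1).
#' @param prevalence Outcome prevalence in (0, 1\].
#' @return Patients per site (integer).
#' @export
required_patients_per_site <- function(event_threshold, prevalence) {
  stopifnot(event_threshold >= 1, prevalence > 0, prevalence <= 1)
  as.integer(round(event_threshold / prevalence))
}

#' @rdname required_patients_per_site
#' @param n_sites Number of sites in the registry.
#' @return `required_registry_size()`: total patients across the registry.
#' @export
required_registry_size <- function(event_threshold, prevalence, n_sites) {
  stopifnot(n_sites >= 1)
  as.integer(n_sites) * required_patients_per_site(event_threshold, prevalence)
}
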