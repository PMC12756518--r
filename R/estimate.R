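#' Rank-based (Mann-Whitney) AUC of a score against a binary outcome
#'
#' @param score Numeric score (higher = more likely an event).
#' @param outcome Binary outcome (0/1 or logical).
#' @return The AUC, or `NA` if either class is empty. Ties in the score
#'   contribute 1/2, as in the Mann-Whitney statistic.
#' @export
rank_auc <- function(score, outcome) {
  outcome <- as.logical(outcome)
  n1 <- as.numeric(sum(outcome))
  n0 <- as.numeric(sum(!outcome))
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the pooled logistic risk model
#'
#' Maximum-likelihood logistic regression of the outcome on the risk score,
#' pooled over all patients with no site or clinician terms — the model
#' used for risk adjustment when benchmarking. The fitted probabilities
#' satisfy the intercept score equation (their sum equals the number of
#' observed events), which is what makes the observed/expected ratio a
#' calibrated standardisation.
#'
#' @param dataset A `registry_dataset`.
#' @return An object of class `risk_model_fit`: list with `intercept`,
#'   `slope`, `fitted_probs`, `converged`, `discrimination_auc`. When the
#'   outcome is degenerate (all events or all non-events) or the fit does
#'   not converge, `converged` is `FALSE` and downstream risk-adjusted
#'   methods are treated as undefined for the replicate.
#' @export
fit_risk_model <- function(dataset) {
  stopifnot(inherits(dataset, "registry_dataset"))
  d <- dataset$patients
  events <- sum(d$outcome)
  if (events == 0L || events == nrow(d)) {
    return(structure(
      list(intercept = NA_real_, slope = NA_real_, fitted_probs = NULL,
           converged = FALSE, discrimination_auc = NA_real_),
      class = "risk_model_fit"
    ))
  }
  fit <- tryCatch(
    glm(outcome ~ risk_score, family = binomial(), data = d),
    error = function(e) NULL,
    warning = function(w) {
      # glm.fit warnings signal separation / non-convergence
      suppressWarnings(glm(outcome ~ risk_score, family = binomial(), data = d))
    }
  )
  if (is.null(fit) || !fit$converged) {
    return(structure(
      list(intercept = NA_real_, slope = NA_real_, fitted_probs = NULL,
           converged = FALSE, discrimination_auc = NA_real_),
      class = "risk_model_fit"
    ))
  }
  probs <- as.numeric(fitted(fit))
  slope <- unname(coef(fit)[2])
  if (is.na(slope)) slope <- 0  # constant risk score: intercept-only model
  structure(
    list(
      intercept = unname(coef(fit)[1]),
      slope = slope,
      fitted_probs = probs,
      converged = TRUE,
      discrimination_auc = rank_auc(probs, d$outcome)
    ),
    class = "risk_model_fit"
  )
}

#' @export
print.risk_model_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<risk_model_fit> not converged\n")
  } else {
    cat(sprintf(
      "<risk_model_fit> logit(p) = %.4f + %.4f * risk_score; AUC %.3f\n",
      x$intercept, x$slope, x$discrimination_auc
    ))
  }
  invisible(x)
}

#' Summarise observed and expected events per site
#'
#' Per site: case volume \eqn{n_j}, observed events \eqn{O_j} and the
#' unadjusted rate \eqn{O_j / n_j}. When a converged risk-model fit is
#' supplied, the expected events are \eqn{E_j = \sum \hat p_i} over the
#' site's patients and the risk-adjusted rate is the indirectly
#' standardised \eqn{(O_j / E_j)\,\bar p}, where \eqn{\bar p} is the pooled
#' patient-level event proportion (the benchmark).
#'
#' @param dataset A `registry_dataset`.
#' @param fit Optional [fit_risk_model()] result.
#' @return A tibble of class `site_summary` with columns `site_id`,
#'   `n_patients`, `observed`, `expected`, `unadjusted_rate`,
#'   `adjusted_rate`, `included` (all `TRUE`; see
#'   [apply_case_volume_minimum()]).
#' @export
summarize_sites <- function(dataset, fit = NULL) {
  stopifnot(inherits(dataset, "registry_dataset"))
  p <- dataset$patients
  n_sites <- nrow(dataset$sites)
  observed <- tabulate(p$site_id[p$outcome == 1L], nbins = n_sites)
  n_patients <- dataset$sites$n_patients
  unadjusted <- ifelse(n_patients > 0, observed / n_patients, NA_real_)

  expected <- rep(NA_real_, n_sites)
  adjusted <- rep(NA_real_, n_sites)
  if (!is.null(fit) && isTRUE(fit$converged)) {
    expected <- as.numeric(
      rowsum(fit$fitted_probs, factor(p$site_id, levels = seq_len(n_sites)))
    )
    pbar <- mean(p$outcome)
    adjusted <- ifelse(expected > 0, observed / expected * pbar, NA_real_)
    adjusted[expected == 0 & observed == 0] <- 0
  }

  out <- tibble::tibble(
    site_id = dataset$sites$site_id,
    n_patients = n_patients,
    observed = observed,
    expected = expected,
    unadjusted_rate = unadjusted,
    adjusted_rate = adjusted,
    included = TRUE
  )
  class(out) <- c("site_summary", class(out))
  out
}

#' Write site summaries to CSV
#'
#' @param summaries A [summarize_sites()] result.
#' @param path Output CSV path.
#' @export
write_site_summaries <- function(summaries, path) {
  utils::write.csv(as.data.frame(summaries), path, row.names = FALSE)
  invisible(path)
}
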