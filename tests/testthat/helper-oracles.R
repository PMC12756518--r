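# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (pmf summation, closed forms, brute-force
# loops) so they share no code path with the implementation they check.

# Smallest k with P(Binomial(n, p0) >= k) <= alpha, by summing the pmf from
# the top down.
bf_upper_threshold <- function(n, p0, alpha) {
  n <- as.integer(n)
  pmf <- dbinom(0:n, n, p0)
  upper_tail <- rev(cumsum(rev(pmf)))  # upper_tail[k + 1] = P(X >= k)
  ok <- which(upper_tail <= alpha)
  if (length(ok) == 0) n + 1L else as.integer(ok[1] - 1L)
}

# Exact lower limit of a two-sided Poisson CI for a mean, given count O.
exact_poisson_lower <- function(O, level = 0.95) {
  ifelse(O == 0, 0, qgamma((1 - level) / 2, O))
}

# Hand-rolled site summary object for unit tests that need exact counts.
toy_summaries <- function(n, observed, expected = NA_real_,
                          included = TRUE) {
  k <- length(n)
  tibble::tibble(
    site_id = seq_len(k),
    n_patients = as.integer(n),
    observed = as.integer(observed),
    expected = rep_len(expected, k),
    unadjusted_rate = observed / n,
    adjusted_rate = NA_real_,
    included = rep_len(included, k)
  )
}

# A small registry built directly (no simulation), for estimation tests.
toy_registry <- function(site_id, clinician_id, risk_score, outcome) {
  n_sites <- max(site_id)
  volumes <- tabulate(site_id, nbins = n_sites)
  structure(
    list(
      patients = tibble::tibble(
        patient_id = seq_along(site_id),
        clinician_id = clinician_id,
        site_id = site_id,
        risk_score = risk_score,
        risk_prob = NA_real_,
        outcome = as.integer(outcome)
      ),
      sites = tibble::tibble(
        site_id = seq_len(n_sites),
        true_outlier = rep(FALSE, n_sites),
        n_patients = volumes
      ),
      provenance = list(seed = NULL, scenario_id = "toy")
    ),
    class = "registry_dataset"
  )
}

# Fast small scenario for end-to-end tests.
small_scenario <- function(...) {
  args <- utils::modifyList(
    list(prevalence = 0.4, n_sites = 12, clinicians_per_site = 2,
         patients_per_clinician = 25, n_replicates = 20, seed = 99L),
    list(...)
  )
  do.call(scenario_config, args)
}
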