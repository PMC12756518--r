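#' Allocate a total count across clusters with gamma-dispersed sizes
#'
#' Draws one gamma weight per cluster, scales the weights to the requested
#' total, and integerises by largest remainder so the sizes sum exactly to
#' `total`. Every cluster receives at least one unit; the excess created by
#' clamping is taken back one unit at a time from the largest clusters.
#' Uses the current RNG state.
#'
#' @param total Total count to distribute (`total >= n_clusters`).
#' @param n_clusters Number of clusters.
#' @param gamma_shape Shape of the gamma weights; the coefficient of
#'   variation of cluster sizes approaches `1/sqrt(gamma_shape)`.
#' @return An integer vector of length `n_clusters`, positive, summing to
#'   `total`.
#' @examples
#' set.seed(1)
#' allocate_cluster_sizes(1000, 10, gamma_shape = 2)
#' @export
allocate_cluster_sizes <- function(total, n_clusters, gamma_shape = 2) {
  stopifnot(n_clusters >= 1, gamma_shape > 0)
  total <- as.integer(total)
  n_clusters <- as.integer(n_clusters)
  if (total < n_clusters) {
    stop("`total` must be at least `n_clusters` (every cluster needs >= 1)")
  }
  if (n_clusters == 1L) return(total)
  w <- rgamma(n_clusters, shape = gamma_shape)
  if (sum(w) == 0) w <- rep(1, n_clusters)
  target <- w / sum(w) * total
  sizes <- as.integer(floor(target))
  short <- total - sum(sizes)
  if (short > 0) {
    idx <- order(target - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[idx] <- sizes[idx] + 1L
  }
  sizes[sizes < 1L] <- 1L
  excess <- sum(sizes) - total
  while (excess > 0L) {
    i <- which.max(sizes)
    sizes[i] <- sizes[i] - 1L
    excess <- excess - 1L
  }
  sizes
}

#' Assign true-outlier status to sites
#'
#' Independent Bernoulli draws, so a given replicate may contain no true
#' outliers (at 25 sites and probability 0.05 that happens in about 28% of
#' replicates). Uses the current RNG state.
#'
#' @param n_sites Number of sites.
#' @param outlier_prob Per-site outlier probability in \[0, 1\].
#' @return A logical vector of length `n_sites`.
#' @export
assign_outlier_status <- function(n_sites, outlier_prob) {
  stopifnot(n_sites >= 1, outlier_prob >= 0, outlier_prob <= 1)
  rbinom(n_sites, 1L, outlier_prob) == 1L
}

#' Simulate one hierarchical registry dataset
#'
#' Generates a three-level registry (patients within clinicians within
#' sites) under the scenario's data-generating mechanism:
#' \enumerate{
#'   \item clinicians are allocated to sites, and patients to clinicians,
#'     with gamma-dispersed cluster sizes conserving the scenario totals;
#'   \item sites are independently assigned true-outlier status;
#'   \item each patient's outcome probability is the inverse logit of
#'     \eqn{\mu + \delta\,1[\mathrm{outlier\ site}] + u_{site} +
#'     v_{clinician} + e_{patient} + \beta x}, with normal random terms at
#'     the stated SDs and a standard-normal risk score \eqn{x};
#'   \item the binary outcome is a Bernoulli draw at that probability.
#' }
#' The result is bitwise reproducible given (`scenario`, `replicate_seed`).
#'
#' @param scenario A [scenario_config()].
#' @param replicate_seed Seed set before any random draw; `NULL` continues
#'   from the current RNG state.
#' @param calibration Optional pre-computed [calibrate_scenario()] result.
#' @return An object of class `registry_dataset`: a list with tibbles
#'   `patients` (patient_id, clinician_id, site_id, risk_score, risk_prob,
#'   outcome) and `sites` (site_id, true_outlier, n_patients), plus a
#'   `provenance` list (seed, scenario id).
#' @examples
#' ds <- simulate_registry(scenario_config(prevalence = 0.4, n_sites = 5,
#'                                         clinicians_per_site = 2,
#'                                         patients_per_clinician = 20),
#'                         replicate_seed = 42)
#' ds
#' @export
simulate_registry <- function(scenario, replicate_seed = NULL,
                              calibration = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (!is.null(replicate_seed)) set.seed(replicate_seed)
  calibration <- calibration %||% calibrate_scenario(scenario)

  n_sites <- scenario$n_sites
  n_clin <- n_sites * scenario$clinicians_per_site
  n_pat <- n_clin * scenario$patients_per_clinician

  clin_sizes <- allocate_cluster_sizes(n_clin, n_sites, scenario$gamma_shape)
  pat_sizes <- allocate_cluster_sizes(n_pat, n_clin, scenario$gamma_shape)
  site_of_clin <- rep.int(seq_len(n_sites), clin_sizes)
  clinician_id <- rep.int(seq_len(n_clin), pat_sizes)
  site_id <- site_of_clin[clinician_id]

  true_outlier <- assign_outlier_status(n_sites, scenario$outlier_prob)
  u_site <- rnorm(n_sites, 0, scenario$sd_site)
  v_clin <- rnorm(n_clin, 0, scenario$sd_clinician)
  e_pat <- if (scenario$sd_patient > 0) rnorm(n_pat, 0, scenario$sd_patient) else 0
  x <- rnorm(n_pat)

  eta <- calibration$mu +
    calibration$delta * as.numeric(true_outlier[site_id]) +
    u_site[site_id] + v_clin[clinician_id] + e_pat +
    calibration$beta * x
  risk_prob <- plogis(eta)
  outcome <- rbinom(n_pat, 1L, risk_prob)
  site_volume <- tabulate(site_id, nbins = n_sites)

  structure(
    list(
      patients = tibble::tibble(
        patient_id = seq_len(n_pat),
        clinician_id = clinician_id,
        site_id = site_id,
        risk_score = x,
        risk_prob = risk_prob,
        outcome = outcome
      ),
      sites = tibble::tibble(
        site_id = seq_len(n_sites),
        true_outlier = true_outlier,
        n_patients = site_volume
      ),
      provenance = list(
        seed = replicate_seed,
        scenario_id = scenario$id,
        calibration = calibration
      )
    ),
    class = "registry_dataset"
  )
}

#' @export
print.registry_dataset <- function(x, ...) {
  cat(sprintf(
    "<registry_dataset> %s patients, %d clinicians, %d sites (%d true outliers)\n",
    format(nrow(x$patients), big.mark = ","),
    length(unique(x$patients$clinician_id)),
    nrow(x$sites), sum(x$sites$true_outlier)
  ))
  cat(sprintf("  observed prevalence %.4f; scenario %s, seed %s\n",
              mean(x$patients$outcome), x$provenance$scenario_id,
              x$provenance$seed %||% "<RNG state>"))
  invisible(x)
}

#' Export a simulated registry as delimited tables
#'
#' Writes the patient table (patient_id, clinician_id, site_id, risk_score,
#' outcome) and the site-truth table (site_id, true_outlier, n_patients) as
#' CSV files.
#'
#' @param dataset A `registry_dataset`.
#' @param patients_path,sites_path Output CSV paths.
#' @return The paths, invisibly.
#' @export
write_registry <- function(dataset, patients_path, sites_path) {
  stopifnot(inherits(dataset, "registry_dataset"))
  pat <- dataset$patients[c("patient_id", "clinician_id", "site_id",
                            "risk_score", "outcome")]
  utils::write.csv(pat, patients_path, row.names = FALSE)
  utils::write.csv(dataset$sites, sites_path, row.names = FALSE)
  invisible(c(patients_path, sites_path))
}

#' Assemble a registry dataset from external tables
#'
#' Builds a `registry_dataset` from a patient-level table (for example a
#' real registry extract read with [utils::read.csv()]) so the estimation
#' and classification stages can run on non-simulated data. True outlier
#' status, if unknown, is recorded as `NA`.
#'
#' @param patients Data frame with columns `patient_id`, `clinician_id`,
#'   `site_id`, `risk_score`, `outcome` (0/1).
#' @param true_outlier Optional logical vector, one element per distinct
#'   site (in sorted site order).
#' @return A `registry_dataset`.
#' @export
registry_from_table <- function(patients, true_outlier = NULL) {
  needed <- c("patient_id", "clinician_id", "site_id", "risk_score", "outcome")
  missing <- setdiff(needed, names(patients))
  if (length(missing)) {
    stop("`patients` is missing columns: ", paste(missing, collapse = ", "))
  }
  stopifnot(all(patients$outcome %in% c(0, 1)))
  site_ids <- sort(unique(patients$site_id))
  # remap ids to 1..K so downstream tabulations are positional
  site_idx <- match(patients$site_id, site_ids)
  clin_ids <- sort(unique(patients$clinician_id))
  clin_idx <- match(patients$clinician_id, clin_ids)
  if (anyDuplicated(unique(data.frame(c = clin_idx, s = site_idx))$c)) {
    stop("each clinician must belong to exactly one site")
  }
  structure(
    list(
      patients = tibble::tibble(
        patient_id = patients$patient_id,
        clinician_id = clin_idx,
        site_id = site_idx,
        risk_score = patients$risk_score,
        risk_prob = NA_real_,
        outcome = as.integer(patients$outcome)
      ),
      sites = tibble::tibble(
        site_id = seq_along(site_ids),
        original_site_id = site_ids,
        true_outlier = true_outlier %||% rep(NA, length(site_ids)),
        n_patients = tabulate(site_idx, nbins = length(site_ids))
      ),
      provenance = list(seed = NULL, scenario_id = "external")
    ),
    class = "registry_dataset"
  )
}
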