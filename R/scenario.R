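#' Define a registry simulation scenario
#'
#' A scenario bundles every parameter of the data-generating mechanism for
#' one simulated clinical quality registry: its size (sites, clinicians per
#' site, patients per clinician), the patient-level outcome prevalence, the
#' true-outlier model, the logit-scale random-variation components, the
#' cluster-size dispersion, the case-volume minimum applied before
#' benchmarking, and the Monte-Carlo settings.
#'
#' Outcome prevalence is the marginal patient-level event probability among
#' non-outlier sites. Sites are independently assigned true-outlier status
#' with probability `outlier_prob`; patients at outlier sites have an
#' underlying prevalence of `outlier_multiplier` times the baseline (on the
#' probability scale, switching to complement scaling where the multiplied
#' value would exceed 1 — see [outlier_logit_shift()]).
#'
#' @param n_sites Number of sites in the registry.
#' @param clinicians_per_site Mean number of clinicians per site; actual
#'   counts are gamma-dispersed around this mean.
#' @param patients_per_clinician Mean number of patients per clinician.
#' @param prevalence Marginal outcome prevalence among non-outlier sites,
#'   in (0, 1). Typical low/mid/high values are 0.05, 0.40 and 0.90.
#' @param outlier_prob Probability that a site is a true outlier.
#' @param outlier_multiplier Prevalence multiplier for outlier sites
#'   (default 2: outlier sites double the outcome prevalence).
#' @param target_risk_auc Target discrimination AUC of the single-covariate
#'   patient risk model, in \[0.5, 1). The risk-score coefficient is
#'   calibrated so a correctly specified logistic model achieves this AUC.
#' @param sd_site,sd_clinician,sd_patient Standard deviations of the
#'   site-, clinician- and patient-level random variation on the logit
#'   scale (all nonnegative).
#' @param gamma_shape Shape of the gamma weights used to allocate
#'   clinicians to sites and patients to clinicians; smaller values give
#'   more dispersed cluster sizes.
#' @param case_volume_minimum Sites with fewer patients are excluded from
#'   benchmarking (and can never be flagged).
#' @param n_replicates Default number of Monte-Carlo replicates for
#'   [run_scenario()].
#' @param seed Master seed for the scenario; replicate seeds are derived
#'   from it.
#' @param id Optional scenario identifier; a descriptive one is built from
#'   the parameters when omitted.
#'
#' @return An object of class `scenario_config` (a named list).
#' @examples
#' sc <- scenario_config(prevalence = 0.4)
#' sc
#' @export
scenario_config <- function(n_sites = 25,
                            clinicians_per_site = 10,
                            patients_per_clinician = 100,
                            prevalence,
                            outlier_prob = 0.05,
                            outlier_multiplier = 2,
                            target_risk_auc = 0.80,
                            sd_site = 0.3,
                            sd_clinician = 0.15,
                            sd_patient = 0,
                            gamma_shape = 2,
                            case_volume_minimum = 0,
                            n_replicates = 200,
                            seed = 1L,
                            id = NULL) {
  stopifnot(
    length(prevalence) == 1, is.numeric(prevalence),
    prevalence > 0, prevalence < 1,
    outlier_prob >= 0, outlier_prob <= 1,
    outlier_multiplier > 0,
    target_risk_auc >= 0.5, target_risk_auc < 1,
    n_sites >= 1, clinicians_per_site >= 1, patients_per_clinician >= 1,
    sd_site >= 0, sd_clinician >= 0, sd_patient >= 0,
    gamma_shape > 0,
    case_volume_minimum >= 0,
    n_replicates >= 1
  )
  cfg <- list(
    n_sites = as.integer(n_sites),
    clinicians_per_site = as.integer(clinicians_per_site),
    patients_per_clinician = as.integer(patients_per_clinician),
    prevalence = prevalence,
    outlier_prob = outlier_prob,
    outlier_multiplier = outlier_multiplier,
    target_risk_auc = target_risk_auc,
    sd_site = sd_site,
    sd_clinician = sd_clinician,
    sd_patient = sd_patient,
    gamma_shape = gamma_shape,
    case_volume_minimum = as.integer(case_volume_minimum),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  )
  cfg$id <- id %||% sprintf(
    "s%d_c%d_p%d_prev%s_cvm%d",
    cfg$n_sites, cfg$clinicians_per_site, cfg$patients_per_clinician,
    format(prevalence, trim = TRUE), cfg$case_volume_minimum
  )
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$id, "\n", sep = "")
  cat(sprintf(
    "  %d sites x %d clinicians/site x %d patients/clinician (%s patients)\n",
    x$n_sites, x$clinicians_per_site, x$patients_per_clinician,
    format(x$n_sites * x$clinicians_per_site * x$patients_per_clinician,
           big.mark = ",")
  ))
  cat(sprintf(
    "  prevalence %.2f, outlier prob %.2f x%.3g, risk AUC target %.2f\n",
    x$prevalence, x$outlier_prob, x$outlier_multiplier, x$target_risk_auc
  ))
  cat(sprintf(
    "  logit SDs: site %.2f, clinician %.2f, patient %.2f; gamma shape %.2f\n",
    x$sd_site, x$sd_clinician, x$sd_patient, x$gamma_shape
  ))
  cat(sprintf("  case volume minimum %d; %d replicates, seed %d\n",
              x$case_volume_minimum, x$n_replicates, x$seed))
  invisible(x)
}

#' Read or write scenario configuration files
#'
#' Scenarios are stored in YAML: either a single mapping of
#' [scenario_config()] fields, or a `scenarios:` list of such mappings.
#'
#' @param path Path to a YAML file.
#' @return `read_scenarios()` returns a list of `scenario_config` objects.
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- if (!is.null(raw$scenarios)) raw$scenarios else list(raw)
  lapply(entries, function(e) do.call(scenario_config, e))
}

#' @rdname read_scenarios
#' @param scenarios A `scenario_config` or a list of them.
#' @export
write_scenarios <- function(scenarios, path) {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  strip <- function(s) lapply(unclass(s), function(v) v)
  yaml::write_yaml(list(scenarios = lapply(scenarios, strip)), path)
  invisible(path)
}
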