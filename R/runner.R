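#' @importFrom rlang .data
NULL

.combinations <- c(
  "unadjusted_control_limits", "adjusted_control_limits",
  "unadjusted_confidence_interval", "adjusted_confidence_interval"
)

#' Run all Monte-Carlo replicates of one scenario
#'
#' For each replicate: simulate a registry, fit the pooled logistic risk
#' model, summarise sites, apply the case-volume minimum, classify outliers
#' under all four method combinations, and score the flags against the
#' known true-outlier status. Replicate seeds are drawn once from the
#' master seed, so replicates are independent and any one of them can be
#' re-simulated on its own; the whole run is bitwise reproducible from the
#' manifest.
#'
#' @param scenario A [scenario_config()].
#' @param n_replicates,seed Override the scenario's replicate count /
#'   master seed.
#' @return An object of class `scenario_result`: list with the `scenario`,
#'   `per_replicate` metrics tibble (one row per replicate x method
#'   combination), `aggregate` ([aggregate_metrics()]), `pooled`
#'   ([pooled_metrics()]), `events_per_site` (mean observed events per site
#'   across replicates) and a `manifest`.
#' @examples
#' \donttest{
#' res <- run_scenario(scenario_config(prevalence = 0.4, n_sites = 10,
#'                                     clinicians_per_site = 2,
#'                                     patients_per_clinician = 25,
#'                                     n_replicates = 20))
#' res
#' }
#' @export
run_scenario <- function(scenario, n_replicates = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  n_replicates <- as.integer(n_replicates %||% scenario$n_replicates)
  seed <- as.integer(seed %||% scenario$seed)
  calibration <- calibrate_scenario(scenario)

  set.seed(seed)
  replicate_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  rows <- vector("list", n_replicates)
  events_per_site <- numeric(n_replicates)
  n_failed_fits <- 0L
  for (r in seq_len(n_replicates)) {
    ds <- simulate_registry(scenario, replicate_seeds[r], calibration)
    fit <- fit_risk_model(ds)
    if (!fit$converged) n_failed_fits <- n_failed_fits + 1L
    summ <- summarize_sites(ds, fit)
    summ <- apply_case_volume_minimum(summ, scenario$case_volume_minimum)
    flags <- classify(summ)
    truth <- ds$sites$true_outlier
    events_per_site[r] <- mean(summ$observed)
    rows[[r]] <- dplyr::bind_rows(lapply(.combinations, function(cmb) {
      m <- replicate_metrics(confusion(flags[[cmb]], truth))
      tibble::tibble(replicate = r, combination = cmb, m)
    }))
  }
  per_replicate <- dplyr::bind_rows(rows)

  structure(
    list(
      scenario = scenario,
      per_replicate = per_replicate,
      aggregate = aggregate_metrics(per_replicate),
      pooled = pooled_metrics(per_replicate),
      events_per_site = mean(events_per_site),
      manifest = list(
        scenario_id = scenario$id,
        scenario = unclass(scenario),
        seed = seed,
        n_replicates = n_replicates,
        n_failed_fits = n_failed_fits,
        package_version = as.character(utils::packageVersion("sitebench")),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$manifest$scenario_id,
      sprintf(" (%d replicates, seed %d)\n",
              x$manifest$n_replicates, x$manifest$seed), sep = "")
  cat(sprintf("  mean observed events/site: %.1f\n", x$events_per_site))
  auc <- x$aggregate[x$aggregate$metric == "roc_auc", ]
  for (i in seq_len(nrow(auc))) {
    cat(sprintf("  ROC AUC %-32s %.3f [%.3f, %.3f] (n=%d)\n",
                auc$combination[i], auc$mean[i], auc$ci_low[i],
                auc$ci_high[i], auc$n_defined[i]))
  }
  invisible(x)
}

#' Build a scenario grid for one parameter sweep
#'
#' Expands one named sweep, crossed with outcome prevalence, into a list of
#' scenarios (the grids are per-sweep crossings, not a full factorial over
#' every parameter). Default sweep values: sites 5/10/25/50/100/250,
#' clinicians per site 2/10/50, patients per clinician 10/100/250, case
#' volume minimum 0/10/50/150/250 (crossed with 250 and 500 patients per
#' site); prevalence 5%/40%/90%. Non-swept parameters sit at the defaults
#' of 25 sites, 10 clinicians per site, 100 patients per clinician, which
#' `base` can override.
#'
#' @param sweep One of `"sites"`, `"clinicians_per_site"`,
#'   `"patients_per_clinician"`, `"case_volume_minimum"`.
#' @param values Sweep values; `NULL` uses the defaults above. A
#'   zero-length vector yields an empty grid.
#' @param prevalence Prevalence values to cross with the sweep.
#' @param patients_per_site Only for the case-volume sweep: mean patients
#'   per site (converted to patients per clinician, so it must be a
#'   multiple of the clinicians per site).
#' @param base Named list of [scenario_config()] arguments overriding the
#'   defaults in every cell.
#' @return A list of `scenario_config` objects in deterministic order
#'   (sweep value, then patients per site, then prevalence).
#' @examples
#' length(build_grid("sites"))                     # 6 x 3 = 18 scenarios
#' length(build_grid("case_volume_minimum"))       # 5 x 2 x 3 = 30
#' @export
build_grid <- function(sweep = c("sites", "clinicians_per_site",
                                 "patients_per_clinician",
                                 "case_volume_minimum"),
                       values = NULL,
                       prevalence = c(0.05, 0.40, 0.90),
                       patients_per_site = c(250, 500),
                       base = list()) {
  sweep <- match.arg(sweep)
  defaults <- list(
    sites = c(5, 10, 25, 50, 100, 250),
    clinicians_per_site = c(2, 10, 50),
    patients_per_clinician = c(10, 100, 250),
    case_volume_minimum = c(0, 10, 50, 150, 250)
  )
  values <- values %||% defaults[[sweep]]
  if (length(values) == 0) return(list())

  make <- function(extra) {
    do.call(scenario_config, utils::modifyList(base, extra))
  }
  grid <- list()
  for (v in values) {
    if (sweep == "case_volume_minimum") {
      for (pps in patients_per_site) {
        cps <- base$clinicians_per_site %||% 10
        if (pps %% cps != 0) {
          stop("patients_per_site must be a multiple of clinicians_per_site")
        }
        for (p in prevalence) {
          grid[[length(grid) + 1L]] <- make(list(
            case_volume_minimum = v, clinicians_per_site = cps,
            patients_per_clinician = pps / cps, prevalence = p
          ))
        }
      }
    } else {
      key <- switch(sweep, sites = "n_sites", sweep)
      for (p in prevalence) {
        extra <- list(prevalence = p)
        extra[[key]] <- v
        grid[[length(grid) + 1L]] <- make(extra)
      }
    }
  }
  grid
}

#' Run a grid of scenarios
#'
#' @param grid A list of [scenario_config()] objects (see [build_grid()]).
#' @param n_replicates Optional replicate-count override for every cell.
#' @param seed Optional master seed; when given, per-scenario seeds are
#'   derived from it, otherwise each scenario uses its own seed.
#' @return A list of `scenario_result` objects, named by scenario id.
#' @export
run_grid <- function(grid, n_replicates = NULL, seed = NULL) {
  seeds <- if (is.null(seed)) {
    vapply(grid, function(s) s$seed, integer(1))
  } else {
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max - 1L, length(grid))
  }
  results <- Map(function(sc, sd) run_scenario(sc, n_replicates, sd),
                 grid, seeds)
  names(results) <- vapply(grid, function(s) s$id, character(1))
  results
}

#' Combine grid results into one tidy metrics table
#'
#' @param results A list of `scenario_result` objects.
#' @return A tibble: scenario parameters, `events_per_site` (mean observed
#'   events per site), then `combination`, `metric`, `mean`, `ci_low`,
#'   `ci_high`, `n_defined`.
#' @export
grid_summary <- function(results) {
  dplyr::bind_rows(lapply(results, function(res) {
    sc <- res$scenario
    dplyr::bind_cols(
      tibble::tibble(
        scenario_id = sc$id,
        n_sites = sc$n_sites,
        clinicians_per_site = sc$clinicians_per_site,
        patients_per_clinician = sc$patients_per_clinician,
        patients_per_site = sc$clinicians_per_site * sc$patients_per_clinician,
        prevalence = sc$prevalence,
        case_volume_minimum = sc$case_volume_minimum,
        events_per_site = res$events_per_site
      ),
      res$aggregate
    )
  }))
}

#' Re-index scenario results by observed events per site
#'
#' The driver of classification accuracy is the number of observed outcome
#' events per site rather than any single size parameter; this view
#' re-keys a set of size-sweep results by expected (`patients_per_site *
#' prevalence`) and empirical mean events per site so accuracy thresholds
#' can be read off directly. Every (scenario, combination) pair contributes
#' exactly one row.
#'
#' @param results A list of `scenario_result` objects from >= 1 sweep.
#' @param metric Metric to tabulate (default `"roc_auc"`).
#' @return A tibble sorted by expected events per site.
#' @export
events_per_site_view <- function(results, metric = "roc_auc") {
  tab <- grid_summary(results)
  tab <- tab[tab$metric == metric, ]
  tab$expected_events_per_site <- tab$patients_per_site * tab$prevalence
  tab <- tab[order(tab$expected_events_per_site, tab$scenario_id,
                   tab$combination), ]
  dplyr::select(tab, dplyr::all_of(c(
    "scenario_id", "prevalence", "patients_per_site",
    "expected_events_per_site", "events_per_site",
    "combination", "metric", "mean", "ci_low", "ci_high", "n_defined"
  )))
}

#' Write a scenario result (or grid) as tidy CSV, plus a JSON manifest
#'
#' @param results A `scenario_result` or list of them.
#' @param metrics_path Output CSV path for the aggregated metrics.
#' @param manifest_path Optional JSON manifest path.
#' @return `metrics_path`, invisibly.
#' @export
write_metrics_csv <- function(results, metrics_path, manifest_path = NULL) {
  if (inherits(results, "scenario_result")) results <- list(results)
  utils::write.csv(as.data.frame(grid_summary(results)), metrics_path,
                   row.names = FALSE)
  if (!is.null(manifest_path)) {
    manifests <- lapply(results, function(r) r$manifest)
    jsonlite::write_json(manifests, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(metrics_path)
}
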