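test_that("a single-replicate run aggregates to that replicate's metrics", {
  sc <- small_scenario(outlier_prob = 0.5)   # guarantee defined sensitivity
  suppressWarnings(res <- run_scenario(sc, n_replicates = 1, seed = 31))
  one <- res$per_replicate[res$per_replicate$combination ==
                             "unadjusted_control_limits", ]
  agg <- res$aggregate[res$aggregate$combination ==
                         "unadjusted_control_limits", ]
  expect_equal(agg$mean[agg$metric == "roc_auc"], one$roc_auc)
  expect_equal(agg$mean[agg$metric == "specificity"], one$specificity)
})

test_that("runs are bitwise reproducible from the manifest seed", {
  sc <- small_scenario()
  r1 <- run_scenario(sc, n_replicates = 15, seed = 77)
  r2 <- run_scenario(sc, n_replicates = r1$manifest$n_replicates,
                     seed = r1$manifest$seed)
  expect_identical(r1$per_replicate, r2$per_replicate)
  expect_identical(r1$aggregate, r2$aggregate)
  expect_identical(r1$events_per_site, r2$events_per_site)
})

test_that("scenario grids expand per the study's combination rules", {
  expect_length(build_grid("sites"), 18)                 # 6 x 3 prevalences
  expect_length(build_grid("case_volume_minimum"), 30)   # 5 x 2 x 3
  expect_length(build_grid("sites", values = numeric(0)), 0)
  expect_error(build_grid("dispersion"), "arg")

  g <- build_grid("sites", values = c(10, 25), prevalence = 0.05)
  expect_equal(vapply(g, function(s) s$n_sites, integer(1)), c(10L, 25L))
  expect_true(all(vapply(g, function(s) s$prevalence, numeric(1)) == 0.05))

  cv <- build_grid("case_volume_minimum", values = 150, prevalence = 0.4)
  expect_equal(vapply(cv, function(s) s$patients_per_clinician, integer(1)),
               c(25L, 50L))
})

test_that("scenario YAML files round-trip", {
  sc <- small_scenario(prevalence = 0.9, case_volume_minimum = 50)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenarios(list(sc, small_scenario()), path)
  back <- read_scenarios(path)
  expect_length(back, 2)
  expect_equal(back[[1]], sc)
})

test_that("events-per-site view re-keys every scenario-combination pair once", {
  grid <- build_grid("patients_per_clinician", values = c(10, 50),
                     prevalence = 0.4,
                     base = list(n_sites = 10, clinicians_per_site = 2,
                                 n_replicates = 10))
  results <- run_grid(grid, seed = 5)
  view <- events_per_site_view(results)
  expect_identical(nrow(view), length(grid) * 4L)
  expect_identical(anyDuplicated(view[, c("scenario_id", "combination")]), 0L)
  # 2 clinicians x {10, 50} patients x 0.4 prevalence = 8 and 40 events/site
  expect_equal(sort(unique(view$expected_events_per_site)), c(8, 40))
  expect_equal(view$events_per_site, view$expected_events_per_site,
               tolerance = 0.2)
})

test_that("accuracy rises with patients per site towards a plateau", {
  lo <- run_scenario(scenario_config(prevalence = 0.05,
                                     patients_per_clinician = 10),
                     n_replicates = 60, seed = 41)
  hi <- run_scenario(scenario_config(prevalence = 0.05,
                                     patients_per_clinician = 100),
                     n_replicates = 60, seed = 41)
  auc <- function(res) {
    a <- res$aggregate
    a$mean[a$metric == "roc_auc" &
             a$combination == "adjusted_control_limits"]
  }
  expect_gt(auc(hi), auc(lo))
})

test_that("metrics CSV export is tidy and complete", {
  res <- run_scenario(small_scenario(), n_replicates = 10, seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  man <- withr::local_tempfile(fileext = ".json")
  write_metrics_csv(res, csv, man)
  tab <- utils::read.csv(csv)
  expect_identical(nrow(tab), 4L * 5L)   # 4 combinations x 5 metrics
  expect_true(all(c("scenario_id", "combination", "metric", "mean",
                    "ci_low", "ci_high", "n_defined") %in% names(tab)))
  expect_true(jsonlite::validate(paste(readLines(man), collapse = "")))
})
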