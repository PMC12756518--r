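test_that("confusion counts conserve the site total and match brute force", {
  expect_identical(
    confusion(rep(FALSE, 25), c(rep(TRUE, 2), rep(FALSE, 23))),
    c(tp = 0L, fp = 0L, tn = 23L, fn = 2L)
  )
  truth <- c(TRUE, FALSE, TRUE)
  expect_identical(confusion(truth, truth)[c("fp", "fn")],
                   c(fp = 0L, fn = 0L))

  set.seed(8)
  for (i in 1:100) {
    k <- sample(3:40, 1)
    flags <- runif(k) < 0.3
    truth <- runif(k) < 0.2
    conf <- confusion(flags, truth)
    # enumeration oracle
    want <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
    for (j in seq_len(k)) {
      cell <- if (flags[j] && truth[j]) "tp" else if (flags[j]) "fp"
              else if (truth[j]) "fn" else "tn"
      want[cell] <- want[cell] + 1L
    }
    expect_identical(conf, want)
    expect_identical(sum(conf), k)
  }

  expect_true(all(is.na(confusion(c(TRUE, NA), c(TRUE, FALSE)))))
})

test_that("replicate metrics handle perfect, degenerate and undefined cases", {
  perfect <- replicate_metrics(c(tp = 2L, fp = 0L, tn = 23L, fn = 0L))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$roc_auc, 1)

  all_flagged <- replicate_metrics(c(tp = 2L, fp = 23L, tn = 0L, fn = 0L))
  expect_equal(all_flagged$sensitivity, 1)
  expect_equal(all_flagged$specificity, 0)
  expect_equal(all_flagged$roc_auc, 0.5)

  # no true outliers: sensitivity and ROC AUC undefined, never 0
  none <- replicate_metrics(c(tp = 0L, fp = 1L, tn = 24L, fn = 0L))
  expect_true(is.na(none$sensitivity))
  expect_true(is.na(none$roc_auc))
  expect_false(is.na(none$specificity))
  # nothing flagged: PPV undefined
  expect_true(is.na(replicate_metrics(c(tp = 0L, fp = 0L, tn = 20L,
                                        fn = 2L))$ppv))
})

test_that("binary ROC AUC equals the trapezoid area of the two-point ROC", {
  set.seed(15)
  for (i in 1:50) {
    conf <- c(tp = sample(0:5, 1), fp = sample(0:10, 1),
              tn = sample(1:30, 1), fn = sample(0:5, 1))
    m <- replicate_metrics(conf)
    if (is.na(m$roc_auc)) next
    tpr <- conf[["tp"]] / (conf[["tp"]] + conf[["fn"]])
    fpr <- conf[["fp"]] / (conf[["fp"]] + conf[["tn"]])
    # trapezoid oracle over (0,0) -> (fpr, tpr) -> (1,1)
    xs <- c(0, fpr, 1); ys <- c(0, tpr, 1)
    trap <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
    expect_equal(m$roc_auc, trap, tolerance = 1e-12)
  }
})

test_that("aggregation averages defined replicates with normal CIs", {
  vals <- c(0.9, 0.8, 1.0, 0.7, 0.85)
  per <- tibble::tibble(
    replicate = 1:5, combination = "adjusted_control_limits",
    tp = 1L, fp = 0L, tn = 23L, fn = 1L,
    sensitivity = vals, specificity = vals, ppv = vals, npv = vals,
    roc_auc = vals
  )
  agg <- aggregate_metrics(per)
  row <- agg[agg$metric == "roc_auc", ]
  expect_equal(row$mean, mean(vals))
  expect_equal(row$ci_low, mean(vals) - 1.96 * sd(vals) / sqrt(5))
  expect_equal(row$n_defined, 5L)

  # permutation invariance over replicates
  perm <- per[sample(5), ]
  expect_equal(aggregate_metrics(perm), agg)

  # identical replicates give a zero-width CI
  per0 <- per; per0[, c("sensitivity", "specificity", "ppv", "npv",
                        "roc_auc")] <- 0.75
  agg0 <- aggregate_metrics(per0)
  expect_true(all(agg0$ci_high - agg0$ci_low < 1e-12))

  # fewer than two defined replicates: warn; mean from the one defined
  # replicate, but no CI
  per_na <- per; per_na$roc_auc <- c(0.9, rep(NA, 4))
  expect_warning(agg_na <- aggregate_metrics(per_na), "fewer than 2")
  row_na <- agg_na[agg_na$metric == "roc_auc", ]
  expect_equal(row_na$mean, 0.9)
  expect_true(is.na(row_na$ci_low))
})

test_that("pooled-count aggregation reproduces hand-summed confusion tables", {
  per <- tibble::tibble(
    replicate = rep(1:3, each = 2),
    combination = rep(c("a", "b"), 3),
    tp = c(1L, 0L, 2L, 1L, 0L, 0L), fp = c(0L, 1L, 1L, 0L, 2L, 1L),
    tn = c(22L, 22L, 20L, 22L, 21L, 22L), fn = c(2L, 2L, 2L, 2L, 2L, 2L),
    sensitivity = NA_real_, specificity = NA_real_, ppv = NA_real_,
    npv = NA_real_, roc_auc = NA_real_
  )
  pooled <- pooled_metrics(per)
  a <- pooled[pooled$combination == "a", ]
  expect_equal(a$sensitivity, 3 / (3 + 6))
  expect_equal(a$specificity, 63 / (63 + 3))
})

test_that("planning arithmetic converts event thresholds to patient volumes", {
  expect_identical(required_patients_per_site(100, 0.05), 2000L)
  expect_identical(required_patients_per_site(100, 0.40), 250L)
  expect_identical(required_patients_per_site(100, 0.90), 111L)
  expect_identical(required_patients_per_site(100, 1), 100L)
  expect_identical(required_registry_size(100, 0.05, 20), 40000L)
})
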