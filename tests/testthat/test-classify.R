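test_that("case-volume minimum excludes exactly the low-volume sites", {
  s <- toy_summaries(n = c(5, 20, 100), observed = c(1, 2, 10))
  expect_true(all(apply_case_volume_minimum(s, 0)$included))
  expect_identical(apply_case_volume_minimum(s, 10)$included,
                   c(FALSE, TRUE, TRUE))
  # proportion included is nonincreasing in the minimum
  set.seed(3)
  s2 <- toy_summaries(n = sample(1:300, 40, replace = TRUE),
                      observed = 0)
  props <- vapply(c(0, 10, 50, 150, 250, 400), function(m) {
    mean(apply_case_volume_minimum(s2, m)$included)
  }, numeric(1))
  expect_true(all(diff(props) <= 0))
})

test_that("exact binomial thresholds match brute-force pmf summation", {
  # n = 1, p0 = 0.5: P(X >= 1) = 0.5 > 0.025, so no count can flag
  expect_identical(exact_binomial_upper_limit(1, 0.5), 2L)

  alpha <- 0.025
  for (p0 in c(0.05, 0.10, 0.40, 0.50, 0.90)) {
    n_grid <- c(1:40, 100, 250, 500)
    got <- exact_binomial_upper_limit(n_grid, p0)
    want <- vapply(n_grid, bf_upper_threshold, integer(1),
                   p0 = p0, alpha = alpha)
    expect_identical(got, want)
  }

  # stochastic ordering: threshold nondecreasing in p0 at fixed n
  for (n in c(10, 57, 200)) {
    ks <- exact_binomial_upper_limit(rep(n, 9), seq(0.1, 0.9, by = 0.1))
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("Byar lower bound tracks the exact Poisson bound", {
  expect_identical(byar_lower_bound(0), 0)
  O <- 1:500
  L <- byar_lower_bound(O)
  expect_true(all(diff(L) > 0))        # strictly increasing
  exact <- exact_poisson_lower(O)
  rel_err <- abs(L[O >= 5] - exact[O >= 5]) / exact[O >= 5]
  expect_lt(max(rel_err), 0.02)        # within 2% of exact for O >= 5
})

test_that("confidence-interval flags behave at the extremes", {
  # zero events can never flag
  s0 <- toy_summaries(n = c(50, 10), observed = c(0, 0), expected = c(5, 1))
  f0 <- flag_confidence_interval(s0, benchmark = 0.05)
  expect_false(any(f0$unadjusted))
  expect_false(any(f0$adjusted))

  # a 100%-rate site is flagged once its volume makes the bound exceed even
  # a 90% benchmark, regardless of its true status
  s1 <- toy_summaries(n = 400, observed = 400, expected = 360)
  f1 <- flag_confidence_interval(s1, benchmark = 0.9)
  expect_true(f1$unadjusted)
  expect_true(f1$adjusted)

  # excluded sites never flag
  s2 <- toy_summaries(n = 400, observed = 400, expected = 360,
                      included = FALSE)
  f2 <- flag_confidence_interval(s2, benchmark = 0.9)
  expect_false(f2$unadjusted)
})

test_that("classification agrees with a from-scratch reimplementation of both rules", {
  set.seed(77)
  for (i in 1:50) {
    k <- sample(5:15, 1)
    n <- sample(20:400, k, replace = TRUE)
    pbar_true <- runif(1, 0.05, 0.6)
    O <- rbinom(k, n, pmin(0.95, pbar_true * runif(k, 0.5, 2.5)))
    E <- pmax(n * pbar_true * runif(k, 0.8, 1.2), 1e-6)
    s <- toy_summaries(n, O, expected = E)
    s <- apply_case_volume_minimum(s, sample(c(0, 50), 1))
    fl <- classify(s)
    pbar <- sum(O[s$included]) / sum(n[s$included])
    z <- qnorm(0.975)
    for (j in which(s$included)) {
      # control limits, from the pmf oracle
      kstar <- bf_upper_threshold(n[j], pbar, 0.025)
      expect_identical(fl$unadjusted_control_limits[j], O[j] >= kstar)
      expect_identical(fl$adjusted_control_limits[j],
                       O[j] / E[j] * pbar * n[j] >= kstar)
      # confidence intervals, Byar formula written out afresh
      byar <- if (O[j] == 0) 0 else {
        max(0, O[j] * (1 - 1 / (9 * O[j]) - z / (3 * sqrt(O[j])))^3)
      }
      expect_identical(fl$unadjusted_confidence_interval[j],
                       byar / n[j] > pbar)
      expect_identical(fl$adjusted_confidence_interval[j],
                       byar / E[j] > 1)
    }
    expect_false(any(c(fl$unadjusted_control_limits[!s$included],
                       fl$adjusted_control_limits[!s$included],
                       fl$unadjusted_confidence_interval[!s$included],
                       fl$adjusted_confidence_interval[!s$included])))
  }
})

test_that("classify flags an injected extreme site under all four combinations", {
  n <- rep(200, 10)
  O <- c(rep(10, 9), 200)            # last site has a 100% rate
  E <- n * 0.05
  s <- toy_summaries(n, O, expected = E)
  fl <- classify(s)
  expect_true(fl$unadjusted_control_limits[10])
  expect_true(fl$adjusted_control_limits[10])
  expect_true(fl$unadjusted_confidence_interval[10])
  expect_true(fl$adjusted_confidence_interval[10])
  expect_false(any(unlist(fl[1:9, 3:6])))

  # sites exactly at the benchmark never flag
  s_eq <- toy_summaries(rep(100, 5), rep(10, 5), expected = rep(10, 5))
  fl_eq <- classify(s_eq)
  expect_false(any(unlist(fl_eq[, 3:6])))
})

test_that("funnel limit curves bracket the benchmark and narrow with volume", {
  lims <- funnel_limits(c(10, 50, 100, 500, 2000), 0.2)
  expect_true(all(lims$upper_rate > 0.2))
  expect_true(all(lims$lower_rate < 0.2))
  expect_true(all(diff(lims$upper_rate) < 0))
  width <- lims$upper_rate - lims$lower_rate
  expect_true(all(diff(width) < 0))
})
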