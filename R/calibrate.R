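#' @importFrom rlang %||%
#' @importFrom stats dnorm qnorm plogis qlogis uniroot rnorm rbinom rgamma
#'   pbinom qbinom dbinom fitted coef glm binomial sd qgamma
NULL

# Fixed quadrature grid for integrals against a standard normal density.
# 4001 points over +/-8 SD keeps errors well below the calibration
# tolerances (2e-3 on prevalence, 5e-3 on AUC).
.norm_grid <- function(n = 4001L, span = 8) {
  x <- seq(-span, span, length.out = n)
  w <- dnorm(x)
  list(x = x, w = w / sum(w))
}

.GRID <- .norm_grid()

# Marginal event probability E[plogis(mu + sigma Z)], Z ~ N(0,1).
.marginal_prevalence <- function(mu, sigma) {
  if (sigma == 0) return(plogis(mu))
  sum(.GRID$w * plogis(mu + sigma * .GRID$x))
}

# Intercept giving a target marginal prevalence at latent normal SD sigma.
.solve_intercept <- function(prevalence, sigma) {
  if (sigma == 0) return(qlogis(prevalence))
  uniroot(function(m) .marginal_prevalence(m, sigma) - prevalence,
          interval = qlogis(prevalence) + c(-1, 1) * (5 + 3 * sigma),
          tol = 1e-10)$root
}

#' Discrimination AUC of the single-covariate logistic risk model
#'
#' For a patient risk score \eqn{x \sim N(0,1)} and outcome model
#' \eqn{logit\,P(Y=1|x) = \mu + \beta x}, with \eqn{\mu} chosen so the
#' marginal prevalence equals `prevalence`, returns the AUC
#' \eqn{P(x_{case} > x_{control})} by numerical integration.
#'
#' @param beta Nonnegative coefficient on the standard-normal risk score.
#' @param prevalence Marginal outcome prevalence in (0, 1).
#' @return The discrimination AUC, in \[0.5, 1).
#' @export
risk_model_auc <- function(beta, prevalence) {
  stopifnot(beta >= 0, prevalence > 0, prevalence < 1)
  if (beta == 0) return(0.5)
  mu <- .solve_intercept(prevalence, beta)
  p <- plogis(mu + beta * .GRID$x)
  w1 <- .GRID$w * p        # case density weights
  w0 <- .GRID$w * (1 - p)  # control density weights
  # P(X0 <= x_i) with midpoint correction at the i-th grid cell
  f0 <- (cumsum(w0) - 0.5 * w0) / sum(w0)
  sum(w1 * f0) / sum(w1)
}

#' Calibrate the risk-score coefficient to a target discrimination AUC
#'
#' Solves for the coefficient \eqn{\beta \ge 0} on a standard-normal risk
#' score such that the correctly specified one-covariate logistic risk
#' model discriminates cases from controls with the requested AUC at the
#' given marginal prevalence. Only the product of the coefficient and the
#' risk-score SD is identified, so the score is fixed at unit variance and
#' the coefficient carries the calibration.
#'
#' @param target_risk_auc Target AUC in \[0.5, 1).
#' @param prevalence Marginal outcome prevalence in (0, 1).
#' @param tol Convergence tolerance on the AUC (default 1e-5).
#' @return The calibrated coefficient (a single nonnegative number).
#' @examples
#' calibrate_risk_effect(0.80, 0.40)
#' @export
calibrate_risk_effect <- function(target_risk_auc, prevalence, tol = 1e-5) {
  stopifnot(target_risk_auc >= 0.5, target_risk_auc < 1,
            prevalence > 0, prevalence < 1)
  if (target_risk_auc == 0.5) return(0)
  upper <- 25
  if (risk_model_auc(upper, prevalence) < target_risk_auc) {
    stop("target_risk_auc not attainable within the search bracket")
  }
  uniroot(function(b) risk_model_auc(b, prevalence) - target_risk_auc,
          interval = c(0, upper), tol = tol)$root
}

#' Calibrate the logit intercept for a target marginal prevalence
#'
#' Random variation on the logit scale attenuates the marginal event
#' probability, so the intercept is not simply `qlogis(prevalence)`.
#' This solves for the intercept \eqn{\mu} such that the marginal outcome
#' probability among non-outlier sites — integrating over the site,
#' clinician and patient random terms and the risk score — equals the
#' target prevalence.
#'
#' @param prevalence Target marginal prevalence in (0, 1).
#' @param beta Risk-score coefficient (see [calibrate_risk_effect()]).
#' @param sd_site,sd_clinician,sd_patient Logit-scale random-variation SDs.
#' @return The intercept (a single number).
#' @examples
#' calibrate_intercept(0.4, beta = 0)          # qlogis(0.4)
#' calibrate_intercept(0.05, beta = 1.2, sd_site = 0.3)
#' @export
calibrate_intercept <- function(prevalence, beta = 0, sd_site = 0,
                                sd_clinician = 0, sd_patient = 0) {
  stopifnot(prevalence > 0, prevalence < 1, beta >= 0,
            sd_site >= 0, sd_clinician >= 0, sd_patient >= 0)
  sigma <- sqrt(beta^2 + sd_site^2 + sd_clinician^2 + sd_patient^2)
  .solve_intercept(prevalence, sigma)
}

#' Logit shift applied to true-outlier sites
#'
#' Outlier sites have an underlying outcome prevalence of
#' `multiplier` times the baseline. On the probability scale the target is
#' \eqn{p_{out} = m p} when \eqn{m p < 1}; where multiplication is
#' impossible (e.g. doubling a 90% prevalence) the complement is scaled
#' instead, \eqn{p_{out} = 1 - (1 - p)/m}, preserving an
#' "m times as extreme" interpretation. The returned shift is
#' \eqn{\delta = logit(p_{out}) - logit(p)}, added to the linear predictor
#' of patients at outlier sites.
#'
#' @param prevalence Baseline prevalence in (0, 1).
#' @param multiplier Positive prevalence multiplier.
#' @return The logit shift (positive for `multiplier > 1`).
#' @examples
#' outlier_logit_shift(0.05, 2)  # logit(0.10) - logit(0.05)
#' outlier_logit_shift(0.90, 2)  # logit(0.95) - logit(0.90)
#' @export
outlier_logit_shift <- function(prevalence, multiplier) {
  stopifnot(prevalence > 0, prevalence < 1)
  if (multiplier <= 0) stop("`multiplier` must be positive")
  p_out <- if (multiplier * prevalence < 1) {
    multiplier * prevalence
  } else {
    1 - (1 - prevalence) / multiplier
  }
  qlogis(p_out) - qlogis(prevalence)
}

#' Calibrate all derived parameters of a scenario
#'
#' Computes the risk-score coefficient, the intercept and the outlier
#' logit shift implied by a scenario's prevalence, target risk-model AUC,
#' random-variation SDs and outlier multiplier. [simulate_registry()] calls
#' this lazily; pre-computing it once per scenario avoids repeating the
#' (deterministic) numerical calibration for every replicate.
#'
#' @param scenario A [scenario_config()].
#' @return A list with elements `beta`, `mu` and `delta`.
#' @export
calibrate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  beta <- calibrate_risk_effect(scenario$target_risk_auc, scenario$prevalence)
  mu <- calibrate_intercept(scenario$prevalence, beta,
                            scenario$sd_site, scenario$sd_clinician,
                            scenario$sd_patient)
  delta <- outlier_logit_shift(scenario$prevalence, scenario$outlier_multiplier)
  list(beta = beta, mu = mu, delta = delta)
}
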