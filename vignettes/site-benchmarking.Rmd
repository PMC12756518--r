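---
title: "Simulating site benchmarking accuracy in clinical quality registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating site benchmarking accuracy in clinical quality registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitebench)
```

## The problem

Clinical quality registries benchmark health providers (sites) by comparing
each site's outcome rate against a population benchmark and flagging sites
that deviate beyond statistical limits — the flagged "outliers" being
underperformers with elevated outcome prevalence. Flagging accuracy depends
heavily on the registry's shape: how many sites, how many patients per
site, how common the outcome is, and whether small sites are excluded by a
case-volume minimum. `sitebench` quantifies that dependence by Monte-Carlo
simulation: it generates registries in which the truly underperforming
sites are known, applies the benchmarking methods a registry would use, and
scores the flags against the truth.

## Data-generating mechanism

Each simulated registry is a three-level hierarchy: patients within
clinicians within sites. For a scenario with $S$ sites, $\bar c$ clinicians
per site and $\bar m$ patients per clinician:

1. **Structure.** The $S\bar c$ clinicians are allocated to sites, and the
   $S\bar c\bar m$ patients to clinicians, proportionally to
   gamma-distributed weights (shape $k$, default 2), integerised by largest
   remainder so totals are conserved and every cluster keeps at least one
   member. The coefficient of variation of cluster sizes is roughly
   $1/\sqrt{k}$, so sites differ substantially in case volume — as real
   registries do.
2. **Truth.** Each site is independently a true outlier with probability
   0.05. A replicate can legitimately contain no outliers (probability
   $\approx 0.28$ at 25 sites).
3. **Outcome model.** Patient $i$ of clinician $j$ at site $s$ has
   $$\operatorname{logit} p_{ijs} = \mu + \delta\,[\text{site } s \text{
   outlier}] + u_s + v_j + e_i + \beta x_{ijs},$$
   with $u_s \sim N(0, \sigma_{site}^2)$, $v_j \sim N(0,
   \sigma_{clin}^2)$, $e_i \sim N(0, \sigma_{pat}^2)$ and a standard-normal
   risk score $x$. The outcome is Bernoulli$(p_{ijs})$.

Three parameters are *calibrated* rather than set directly:

- $\beta$ (risk-score effect) is solved so the one-covariate logistic risk
  model discriminates at a target AUC (default 0.80) at the scenario's
  prevalence. Only the product of coefficient and risk-score SD is
  identified, so the score is fixed at unit variance.
- $\mu$ (intercept) is solved so the *marginal* prevalence among
  non-outlier sites equals the target: random variation on the logit scale
  attenuates the marginal probability, so $\mu < \operatorname{logit}(p)$
  whenever any variance component is positive.
- $\delta$ (outlier effect) makes outlier sites' underlying prevalence
  `outlier_multiplier` (default 2) times baseline:
  $\delta = \operatorname{logit}(mp) - \operatorname{logit}(p)$. Doubling
  is impossible on the probability scale once $mp \ge 1$, so there the
  *complement* is scaled instead, $p_{out} = 1 - (1-p)/m$ (doubling a 90%
  prevalence yields 95%) — preserving a "twice as extreme" reading at high
  prevalence.

Both calibrations use deterministic quadrature against the normal density
(4001 nodes over $\pm 8$ SD) and `uniroot`, reproducing the targets to well
under 0.002 on the prevalence scale and 0.005 on the AUC scale; Monte-Carlo
oracles in the test suite confirm both at $n \ge 5\times10^5$.

### Default parameter values

Registry-shape defaults are 25 sites, 10 clinicians/site, 100
patients/clinician. The variance components deserve comment because they
control how hard the classification task is. We use $\sigma_{site} = 0.3$,
$\sigma_{clin} = 0.15$, $\sigma_{pat} = 0$ on the logit scale.
$\sigma_{site} = 0.3$ corresponds to a median odds ratio of about 1.33,
typical of between-hospital variation reported in provider-profiling
studies; clinician variation is taken at half that, and no extra-binomial
patient-level noise is added (the Bernoulli draw already supplies
patient-level randomness — `sd_patient` exists for sensitivity analysis).
With these values the outlier shift ($\delta \approx 0.75$ at 5%
prevalence) is visible but not trivially separable from ordinary
between-site variation, which is exactly the regime in which benchmarking
accuracy becomes an interesting quantity. Substantially smaller components
(e.g. $\sigma_{site} = 0.1$) make the task nearly noiseless — flagging
approaches perfection at realistic volumes — while larger ones drown the
outlier signal; all components are scenario parameters, so sweeps over them
are one `scenario_config()` argument away.

## Benchmarking and classification methods

Four method combinations are evaluated, the cross of two site estimates
with two flagging techniques. The benchmark $\bar p$ is the pooled
patient-level event proportion over included sites.

**Estimates.**

- *Unadjusted*: $O_j / n_j$.
- *Risk-adjusted*: a pooled logistic regression of outcome on risk score
  (no site terms) supplies per-patient fitted probabilities; site expected
  events are $E_j = \sum \hat p_i$ and the indirectly standardised rate is
  $(O_j/E_j)\,\bar p$. The MLE score equation guarantees
  $\sum_j E_j = \sum_j O_j$. The model is fitted on **all** patients,
  including those at sites later excluded by a case-volume minimum:
  exclusion is a benchmarking rule, not a modelling rule.

**Techniques.**

- *95% exact binomial control limits* (funnel plot): a site is flagged
  when its event count reaches the smallest $k^*$ with
  $P(\mathrm{Bin}(n_j, \bar p) \ge k^*) \le 0.025$. Adjusted estimates are
  placed on the funnel at the site's own case volume, i.e.
  $(O_j/E_j)\bar p\, n_j$ is compared with $k^*$. No mid-$p$ or
  interpolation is applied; the rule is the pure exact tail.
- *95% Byar-approximation confidence intervals*: the lower bound of the
  exact Poisson interval for $O_j$ is approximated by
  $L = O(1 - 1/(9O) - z/(3\sqrt{O}))^3$; a site is flagged when
  $L/n_j > \bar p$ (unadjusted) or $L/E_j > 1$ (adjusted). Treating a
  binomial count as Poisson is the standard practice for standardised
  ratios and is accurate in the small-rate regime; at high prevalence it is
  conservative, which is visible in the results as weak
  confidence-interval sensitivity at 90% prevalence.

Only the *upper* tail flags: outliers are defined as underperformers, so
unusually good sites are never flagged. "95%" is read in the funnel-plot
convention — a two-sided band with 2.5% in the flagging tail.

## Scoring

Flags are scored per replicate against the known truth. Excluded sites are
unflagged negatives — this is precisely why case-volume minimums cost
accuracy: a true outlier below the minimum is an automatic false negative.
Sensitivity, specificity, PPV and NPV follow the usual confusion-matrix
definitions, with undefined ratios (no true outliers; nothing flagged)
recorded as missing, never coerced to zero. The ROC AUC of a hard
classifier is the two-point trapezoid value
$(\text{sens}+\text{spec})/2$ — no threshold sweep exists for a binary
flag, so this is the only AUC available, and it equals the trapezoidal
area under the $(0,0)\!-\!(\mathrm{FPR},\mathrm{TPR})\!-\!(1,1)$ curve.

Replicate metrics are averaged over the replicates where they are defined,
with normal-approximation 95% CIs ($\pm 1.96\,\mathrm{sd}/\sqrt{n}$); a
mean needs one defined replicate, a CI two. Because the defined-only
policy is a choice (about 28% of default-scenario replicates have no
outlier to detect), a pooled-counts variant — summing confusion tables over
replicates before computing metrics — is always co-reported in
`scenario_result$pooled`.

## Scenario grids and problem sizes

`build_grid()` expands the per-parameter sweeps crossed with prevalence
$\{0.05, 0.40, 0.90\}$: sites $\{5,10,25,50,100,250\}$, clinicians/site
$\{2,10,50\}$, patients/clinician $\{10,100,250\}$, and case-volume minimum
$\{0,10,50,150,250\}$ crossed with 250 and 500 patients/site. Grids are
per-sweep crossings (the combination columns of the study design), not a
full factorial over everything at once.

The package default is 200 replicates per scenario, which puts the Monte-
Carlo standard error of a mean ROC AUC near 0.01 — small relative to the
10-plus-point effects under study — and keeps a full scenario in the tens
of seconds on one core; 1000 replicates reproduces the original study's
precision when wanted (`n_replicates = 1000`). The acceptance script and
test suite run at 200.

## Determinism

One master seed per run; replicate seeds are drawn once from it, so
replicates are independent, the whole run is bitwise reproducible from the
manifest (`scenario_result$manifest`), and any single replicate can be
re-simulated in isolation via its recorded seed. Calibration is
deterministic (no RNG), so it never perturbs the seed stream.

## What the simulation does and does not show

The generator mimics the *structure* of registry data — clustering,
dispersed case volumes, case-mix-driven outcome risk, a known outlier
mechanism — so conclusions about *relative* method performance and about
volume/prevalence thresholds transfer well. Known gaps:

- Risk scores are iid standard normal across all patients: there is no
  between-site case-mix variation. Consequently $E_j \approx n_j \bar p$
  and risk adjustment changes little *in these simulations*; in real
  registries sites differ systematically in case mix, which is where risk
  adjustment earns the large accuracy gains reported in comparative
  studies. A `sitebench` sweep therefore understates the adjusted-vs-
  unadjusted gap relative to practice.
- The risk model is always correctly specified with a "good" fit
  (AUC 0.80); miscalibrated or weak risk models will shrink the benefit of
  adjustment.
- One binary outcome, one risk factor, site-level benchmarking only;
  time-to-event outcomes, composite indicators and clinician-level
  profiling are out of scope.
- Exact variance-component and gamma-dispersion values in real registries
  vary; the defaults here are realism-based choices (see above), and any
  quantitative claim that depends on them should be read with that
  sensitivity in mind.

## A worked example

```{r example, eval = FALSE}
sc <- scenario_config(prevalence = 0.05)   # 25 x 10 x 100, 5% prevalence
res <- run_scenario(sc, n_replicates = 200, seed = 101)
res
#> <scenario_result> s25_c10_p100_prev0.05_cvm0 (200 replicates, seed 101)
#>   mean observed events/site: 52.5
#>   ROC AUC adjusted_confidence_interval     0.850 [0.824, 0.876] (n=153)
#>   ROC AUC adjusted_control_limits          0.850 [0.824, 0.875] (n=153)
#>   ROC AUC unadjusted_confidence_interval   0.845 [0.819, 0.872] (n=153)
#>   ROC AUC unadjusted_control_limits        0.847 [0.821, 0.874] (n=153)
```

At 5% prevalence the default registry averages only ~52 events per site —
below the 100–150 events/site needed for peak accuracy, which the
planning helpers translate into volumes:

```{r planning}
required_patients_per_site(100, 0.05)
required_patients_per_site(100, 0.40)
required_registry_size(100, 0.05, n_sites = 20)
```

A funnel plot of one simulated registry:

```{r funnel, eval = FALSE}
ds <- simulate_registry(sc, replicate_seed = 42)
s <- summarize_sites(ds, fit_risk_model(ds))
plot_funnel(s, estimate = "adjusted")
```
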