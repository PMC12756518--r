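Package: sitebench
Title: Accuracy of Site Benchmarking and Outlier Classification in
    Clinical Quality Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation toolkit for assessing how accurately clinical
    quality registries can flag underperforming sites (outliers) when
    benchmarking provider outcome rates. Generates hierarchical
    three-level registry data (patients within clinicians within sites)
    with known true-outlier sites, computes unadjusted and risk-adjusted
    (indirectly standardised) site rates, classifies outliers with 95%
    exact binomial control limits and Byar-approximation Poisson
    confidence intervals, and scores classification accuracy
    (sensitivity, specificity, predictive values, ROC AUC) over
    Monte-Carlo replicates across registry-size, outcome-prevalence and
    case-volume-minimum scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
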