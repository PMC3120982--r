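Package: calipermatch
Title: Caliper Width Selection for Propensity-Score Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying and applying caliper matching on the logit of
    the propensity score. Implements greedy nearest-neighbor pair matching
    without replacement within calipers defined as a multiple (gamma) of the
    pooled standard deviation of the logit propensity score, matched-pair
    estimators for risk differences (McNemar-based inference) and differences
    in means (paired t), calibrated data-generating processes that induce a
    specified average treatment effect in the treated (ATT) for binary and
    continuous outcomes, and a Monte Carlo engine that evaluates bias
    reduction, mean squared error, confidence-interval coverage and type I
    error across a grid of caliper widths. Includes a gamma-sweep workflow
    for user-supplied cohorts and a synthetic heart-failure-like cohort
    generator for demonstrations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
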