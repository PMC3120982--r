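# calipermatch

Caliper width selection for propensity-score matching.

When observational cohorts are pair-matched on the propensity score, the
analyst must choose how close a match has to be: the *caliper* is the
maximum allowed difference in the logit of the propensity score within a
pair, expressed as a multiple γ of the pooled standard deviation of the
logit propensity score,

```
caliper = γ · sqrt((s²_treated + s²_control) / 2).
```

Narrow calipers give better-matched pairs (less residual confounding bias)
but discard treated subjects and inflate variance; wide calipers keep
everyone but tolerate poor matches. `calipermatch` provides the machinery to
study and apply this trade-off:

* **Matching** — maximum-likelihood propensity model, logit transform,
  greedy nearest-neighbor 1:1 matching without replacement within a caliper
  (compiled `O(n log n)` matcher), and a γ-grid sweep that forms the classic
  50 matched samples for γ = 0.05, 0.10, …, 2.50.
* **Estimation** — matched-pair risk differences with the
  correlated-proportions variance and McNemar's test, paired-t differences
  in means, crude (unmatched) estimators, and standardized-difference
  balance diagnostics.
* **Calibrated data generation** — simulated cohorts (default n = 10,000,
  25% treated) with 10 covariates under five joint-distribution scenarios,
  logistic treatment assignment, and binary or continuous outcomes whose
  conditional effect parameter β is root-found so the marginal ATT (average
  treatment effect in the treated) equals a prescribed risk difference —
  exploiting the collapsibility of risk differences — or equals β directly
  for differences in means.
* **Monte Carlo engine** — replicated studies summarising bias, percent
  bias reduction over the crude estimator, MSE, 95% CI coverage and type I
  error per γ, with binomial significance bands; this is the framework that
  identifies γ ≈ 0.2 as the MSE-optimal caliper when covariates are
  continuous.
* **Apply workflow** — the same γ sweep on a user-supplied cohort CSV, plus
  a synthetic heart-failure-like demonstration cohort (~7,600 subjects,
  27.3% treated, 27.7% one-year mortality, 28 mixed covariates).

## Worked example

Sweep calipers over the bundled synthetic cohort, where a protective
exposure (conditional odds ratio 0.75) is entangled with 28 baseline
covariates:

```r
library(calipermatch)

cohort <- generate_fixture(n = 7613, seed = 42)
rep <- apply_sweep(cohort, fixture_schema(),
                   gammas = c(0.1, 0.2, 0.5, 1, 2.5), seed = 1)
rep
#> Caliper sweep over 5 gamma values
#>  gamma n_pairs estimate      se   ci_low  ci_high   p_value
#>    0.1    1954 -0.04862 0.01356 -0.07520 -0.02203 0.0003531
#>    0.2    1961 -0.04742 0.01350 -0.07388 -0.02097 0.0004608
#>    0.5    1967 -0.04779 0.01348 -0.07422 -0.02136 0.0004113
#>    1.0    1970 -0.04772 0.01348 -0.07414 -0.02129 0.0004191
#>    2.5    1971 -0.04769 0.01346 -0.07407 -0.02132 0.0004113
```

Each row is one matched analysis: at γ = 0.2, 1,961 of the ~1,970 treated
subjects found a control within the caliper, and the matched-pair risk
difference estimates that the exposure lowers one-year mortality by 4.7
percentage points (95% CI −7.4 to −2.1, McNemar p = 0.0005). Balance
diagnostics confirm why the estimates are trustworthy:

```r
pre  <- subset(rep$balance, is.na(gamma))
post <- subset(rep$balance, gamma == 0.2)
mean(pre$std_difference)   # 0.069  (raw cohort)
mean(post$std_difference)  # 0.012  (after matching at gamma = 0.2)
```

A simulation study runs the same machinery over replicated calibrated
cohorts:

```r
spec <- study_spec("independent_normal", "binary", true_effect = -0.05,
                   n_replicates = 250, gammas = c(0.1, 0.2, 0.5, 1, 2.5),
                   master_seed = 1)
tab <- run_study(spec)          # calibrates beta, then simulates
optimal_gamma(tab, "mse")       # MSE-minimising caliper on this grid
```

A thin command-line wrapper with `simulate`, `calibrate`, `apply` and
`fixture` subcommands is installed at `inst/cli/calipermatch.R`.

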