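#' Specify a Monte Carlo study
#'
#' Bundles the design of one simulation study: covariate scenario, outcome
#' kind, target ATT, cohort size, replicate count, gamma grid and master
#' seed. The reference design uses 1,000 replicates of 10,000 subjects and
#' the 50-point gamma grid; the default here is a scaled-down profile (250
#' replicates) suitable for routine runs.
#'
#' @param scenario Covariate scenario name or [covariate_scenario()].
#' @param outcome_kind `"binary"` or `"continuous"`.
#' @param true_effect Target ATT (risk difference or mean difference).
#' @param n_subjects Cohort size per replicate.
#' @param n_replicates Number of Monte Carlo replicates.
#' @param gammas Gamma grid for the caliper sweep.
#' @param master_seed Integer master seed; every replicate draws from its own
#'   stream derived from `(master_seed, replicate_index)`, so results do not
#'   depend on execution order.
#' @param coeffs Optional pre-calibrated [default_coefficients()] object;
#'   when `NULL`, [run_study()] calibrates via [calibrate_coefficients()].
#' @param calibration_draws MC draws used for calibration when needed.
#' @return Object of class `study_spec`.
#' @export
study_spec <- function(scenario, outcome_kind, true_effect,
                       n_subjects = 10000, n_replicates = 250,
                       gammas = default_gamma_grid(), master_seed = 1L,
                       coeffs = NULL, calibration_draws = 1e6) {
  outcome_kind <- match.arg(outcome_kind, c("binary", "continuous"))
  stopifnot(n_replicates >= 1, all(gammas > 0), length(gammas) >= 1)
  structure(
    list(scenario = as_scenario(scenario), outcome_kind = outcome_kind,
         true_effect = true_effect, n_subjects = as.integer(n_subjects),
         n_replicates = as.integer(n_replicates), gammas = gammas,
         master_seed = as.integer(master_seed), coeffs = coeffs,
         calibration_draws = calibration_draws),
    class = "study_spec"
  )
}

#' @export
print.study_spec <- function(x, ...) {
  cat(sprintf("Study: %s / %s outcome, ATT = %g, n = %d x %d replicates, %d gammas\n",
              x$scenario$name, x$outcome_kind, x$true_effect, x$n_subjects,
              x$n_replicates, length(x$gammas)))
  invisible(x)
}

#' Calibrate the coefficients of a study specification
#'
#' Fills `spec$coeffs` using [calibrate_coefficients()] if not already set.
#' The calibration seed is derived from the master seed so the whole study is
#' reproducible from `master_seed` alone.
#'
#' @param spec A [study_spec()].
#' @return The spec with `coeffs` populated.
#' @export
calibrate_spec <- function(spec) {
  if (!is.null(spec$coeffs)) return(spec)
  spec$coeffs <- calibrate_coefficients(
    spec$scenario, spec$outcome_kind, spec$true_effect,
    mc_draws = spec$calibration_draws,
    seed = derive_seed(spec$master_seed, 0L)
  )
  spec
}

# Deterministic sub-seed from (master seed, index), kept inside 32-bit range.
derive_seed <- function(master_seed, index) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L,
                                    index + 1L)[index + 1L])
}

replicate_seeds <- function(master_seed, n_replicates) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L,
                                    n_replicates + 1L))[-1L]
}

#' Run one Monte Carlo replicate
#'
#' Generates one cohort, fits the propensity model, matches at every gamma in
#' the spec's grid (one shared treated processing order per replicate) and
#' computes the matched and crude effect estimates. A pure function of
#' `(spec, replicate_index)`: results are identical whatever the execution
#' order of replicates.
#'
#' @param spec A calibrated [study_spec()] (see [calibrate_spec()]).
#' @param replicate_index Replicate number, 1-based.
#' @return List with `gamma_estimates` (data frame: one row per gamma with
#'   the `effect_estimate` fields; `NA` estimates where a gamma produced no
#'   pairs) and `crude` (an `effect_estimate`).
#' @export
run_replicate <- function(spec, replicate_index) {
  if (is.null(spec$coeffs)) {
    stop("spec has no calibrated coefficients; run calibrate_spec() first",
         call. = FALSE)
  }
  seed <- replicate_seeds(spec$master_seed, replicate_index)[replicate_index]
  with_seed(seed, {
    cohort <- simulate_cohort(spec$scenario, spec$coeffs, spec$n_subjects)
    fit <- fit_propensity(cohort$covariates, cohort$z)
    matches <- match_gamma_grid(fit$logit_ps, cohort$z, spec$gammas)
    est <- lapply(matches, function(m) {
      if (nrow(m$pairs) == 0) return(NULL)
      if (spec$outcome_kind == "binary") {
        matched_risk_difference(pair_table(m, cohort$y))
      } else {
        if (nrow(m$pairs) < 2) return(NULL)
        matched_mean_difference(m, cohort$y)
      }
    })
    estimand <- if (spec$outcome_kind == "binary") "risk_difference"
                else "mean_difference"
    rows <- lapply(seq_along(spec$gammas), function(i) {
      e <- est[[i]]
      if (is.null(e)) {
        data.frame(gamma = spec$gammas[i], estimate = NA_real_, se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                   n_pairs = 0L)
      } else {
        cbind(gamma = spec$gammas[i],
              as.data.frame(e)[c("estimate", "se", "ci_low", "ci_high",
                                 "p_value", "n_pairs")])
      }
    })
    list(gamma_estimates = do.call(rbind, rows),
         crude = crude_effect(cohort$z, cohort$y, estimand))
  })
}

#' Percent reduction in bias due to matching
#'
#' `100 * (|bias_crude| - |bias_matched|) / |bias_crude|`. Positive values
#' mean matching removed bias; a matched bias exceeding the crude bias gives
#' a negative value, and an estimator that overshoots to the exact opposite
#' of the crude bias scores 0.
#'
#' @param bias_crude Bias of the crude estimator (nonzero).
#' @param bias_ps Bias of the matched estimator.
#' @return Percent, or `NA` when `|bias_crude| < 1e-12` (undefined).
#' @export
pct_bias_reduction <- function(bias_crude, bias_ps) {
  out <- 100 * (abs(bias_crude) - abs(bias_ps)) / abs(bias_crude)
  out[rep_len(abs(bias_crude) < 1e-12, length(out))] <- NA_real_
  out
}

#' Binomial significance band around a nominal rate
#'
#' Normal-approximation acceptance interval for an empirical proportion based
#' on `n_replicates` Monte Carlo replicates:
#' `nominal +/- 1.959964 * sqrt(nominal * (1 - nominal) / n_replicates)`.
#' With 1,000 replicates this gives (0.0365, 0.0635) around 0.05 and
#' (0.9365, 0.9635) around 0.95: empirical rates outside the band differ
#' significantly from nominal.
#'
#' @param nominal Nominal rate (e.g. 0.05 or 0.95).
#' @param n_replicates Number of replicates.
#' @return Numeric vector `c(low, high)`.
#' @export
significance_band <- function(nominal, n_replicates) {
  half <- Z975 * sqrt(nominal * (1 - nominal) / n_replicates)
  c(low = nominal - half, high = nominal + half)
}

#' Aggregate replicate estimates into a metric table
#'
#' Computes, per gamma (plus one crude row): mean estimate, bias, percent
#' bias reduction relative to the crude estimator, MSE, empirical coverage of
#' the 95% CIs, rejection rate at the 0.05 level, and mean pair count.
#' Replicates where a gamma yielded no pairs are excluded from that gamma's
#' aggregates (`n_failed` counts them). Aggregation is a symmetric function
#' of the replicates, so it does not depend on their order.
#'
#' @param spec The [study_spec()] that produced the replicates.
#' @param replicates List of [run_replicate()] results.
#' @return A `metric_table` data frame; replicate-level estimates are kept in
#'   `attr(, "replicates")`.
#' @export
aggregate_replicates <- function(spec, replicates) {
  true <- spec$true_effect
  long <- do.call(rbind, lapply(seq_along(replicates), function(i) {
    cbind(replicate = i, replicates[[i]]$gamma_estimates)
  }))
  crude <- do.call(rbind, lapply(replicates, function(r) as.data.frame(r$crude)))

  summarise <- function(d) {
    ok <- !is.na(d$estimate)
    e <- d$estimate[ok]
    data.frame(
      mean_estimate  = mean(e),
      bias           = mean(e) - true,
      mse            = mean((e - true)^2),
      coverage       = mean(d$ci_low[ok] <= true & true <= d$ci_high[ok]),
      rejection_rate = mean(d$p_value[ok] < 0.05),
      mean_n_pairs   = mean(d$n_pairs[ok]),
      n_used         = sum(ok),
      n_failed       = sum(!ok)
    )
  }

  crude_row <- summarise(crude)
  bias_crude <- crude_row$bias
  glev <- sort(unique(long$gamma))
  per_gamma <- do.call(rbind, lapply(split(long, factor(long$gamma, glev)),
                                     summarise))
  per_gamma <- cbind(gamma = glev, per_gamma)
  per_gamma$pct_bias_reduction <- pct_bias_reduction(bias_crude, per_gamma$bias)
  crude_row <- cbind(gamma = NA_real_, crude_row)
  crude_row$pct_bias_reduction <- NA_real_

  out <- rbind(per_gamma, crude_row)
  out <- cbind(scenario = spec$scenario$name, outcome_kind = spec$outcome_kind,
               true_effect = true, out)
  rownames(out) <- NULL
  class(out) <- c("metric_table", "data.frame")
  attr(out, "replicates") <- long
  attr(out, "crude_replicates") <- crude
  out
}

#' Run a full Monte Carlo study
#'
#' Calibrates the spec if necessary, runs all replicates and aggregates them.
#'
#' @param spec A [study_spec()].
#' @param progress Print a dot every 25 replicates to stderr.
#' @return A `metric_table` (see [aggregate_replicates()]); the calibrated
#'   spec is attached as `attr(, "spec")`.
#' @export
run_study <- function(spec, progress = FALSE) {
  spec <- calibrate_spec(spec)
  reps <- vector("list", spec$n_replicates)
  for (i in seq_len(spec$n_replicates)) {
    reps[[i]] <- run_replicate(spec, i)
    if (progress && i %% 25 == 0) cat(".", file = stderr())
  }
  if (progress) cat("\n", file = stderr())
  out <- aggregate_replicates(spec, reps)
  attr(out, "spec") <- spec
  out
}

#' Optimal gamma under a Monte Carlo criterion
#'
#' Selects the gamma minimising MSE (or maximising percent bias reduction)
#' in a metric table; ties are broken toward the smallest gamma.
#'
#' @param table A `metric_table` from [aggregate_replicates()].
#' @param criterion `"mse"` or `"bias_reduction"`.
#' @return The selected gamma value.
#' @export
optimal_gamma <- function(table, criterion = c("mse", "bias_reduction")) {
  criterion <- match.arg(criterion)
  tab <- table[!is.na(table$gamma), ]
  tab <- tab[order(tab$gamma), ]
  score <- if (criterion == "mse") tab$mse else -tab$pct_bias_reduction
  tab$gamma[which.min(score)]  # which.min takes the first (smallest gamma) tie
}
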