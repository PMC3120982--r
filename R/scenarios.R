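#' Covariate scenario definitions
#'
#' The simulation design uses 10 baseline covariates whose joint distribution
#' follows one of five scenarios: all independent standard normal, exchangeably
#' correlated normal (pairwise correlation 0.25), two mixed designs (5 or 9
#' Bernoulli(0.5) covariates, the remainder standard normal), or all 10
#' Bernoulli(0.5).
#'
#' @param name One of `"independent_normal"`, `"correlated_normal"`,
#'   `"mixed_5b5n"`, `"mixed_9b1n"`, `"all_binary"`.
#' @return An object of class `covariate_scenario` with fields `name`,
#'   `correlation`, `n_binary`, `bernoulli_p` and `n_covariates` (always 10).
#'   Binary covariates occupy the leading columns.
#' @examples
#' covariate_scenario("mixed_5b5n")
#' @export
covariate_scenario <- function(name = c("independent_normal",
                                        "correlated_normal",
                                        "mixed_5b5n",
                                        "mixed_9b1n",
                                        "all_binary")) {
  if (is.character(name) && length(name) == 1L &&
      !name %in% eval(formals(covariate_scenario)$name)) {
    stop("unknown covariate scenario: ", name, call. = FALSE)
  }
  name <- match.arg(name)
  n_binary <- switch(name,
    independent_normal = 0L,
    correlated_normal  = 0L,
    mixed_5b5n         = 5L,
    mixed_9b1n         = 9L,
    all_binary         = 10L
  )
  structure(
    list(
      name         = name,
      correlation  = if (name == "correlated_normal") 0.25 else 0,
      n_binary     = n_binary,
      bernoulli_p  = 0.5,
      n_covariates = 10L
    ),
    class = "covariate_scenario"
  )
}

#' @export
print.covariate_scenario <- function(x, ...) {
  cat("Covariate scenario:", x$name, "\n")
  cat("  ", x$n_covariates - x$n_binary, "standard normal,",
      x$n_binary, sprintf("Bernoulli(%g)", x$bernoulli_p), "covariates\n")
  if (x$correlation > 0) {
    cat("   pairwise correlation", x$correlation, "\n")
  }
  invisible(x)
}

as_scenario <- function(scenario) {
  if (inherits(scenario, "covariate_scenario")) return(scenario)
  covariate_scenario(scenario)
}

#' Coefficient sets for the treatment and outcome models
#'
#' Ten covariate coefficients are organised in four effect-size tiers: three
#' low, three medium, three high, one very high (covariates 1-3, 4-6, 7-9 and
#' 10 respectively). For the logistic (treatment and binary-outcome) models
#' the tier values are `log(1.1)`, `log(1.25)`, `log(1.5)`, `log(2)`; for the
#' continuous-outcome linear model they are 1.1, 1.25, 1.5 and 2 on the
#' outcome scale, with residual variance `sigma2 = 127.6056` chosen so that
#' the covariates explain 13% of outcome variation (R^2 = 0.13).
#'
#' @param outcome_kind `"binary"` or `"continuous"`; selects the scale of the
#'   outcome-model coefficients, default intercept and `sigma2`.
#' @param intercept_treat Treatment-model intercept (log-odds). Usually left
#'   `NA` and solved by [calibrate_treatment_intercept()] to hit the target
#'   treatment prevalence (0.25 in the reference design).
#' @param intercept_outcome Outcome-model intercept. Defaults to
#'   `log(0.29/0.71)` (binary; an untreated event probability of about 0.29)
#'   or 0 (continuous).
#' @param beta Conditional treatment effect: log-odds ratio (binary) or mean
#'   shift (continuous). Usually solved by [calibrate_beta()] for binary
#'   outcomes; for continuous outcomes the ATT equals `beta` directly.
#' @param sigma2 Residual outcome variance (continuous outcomes only).
#' @return An object of class `coefficient_set` with fields `outcome_kind`,
#'   `treat_coefs` (length 10, log-odds), `outcome_coefs` (length 10),
#'   `intercept_treat`, `intercept_outcome`, `beta`, `sigma2` and `tiers`.
#' @examples
#' cs <- default_coefficients("continuous")
#' sum(cs$outcome_coefs^2)  # 19.0675
#' @export
default_coefficients <- function(outcome_kind = c("binary", "continuous"),
                                 intercept_treat = NA_real_,
                                 intercept_outcome = NULL,
                                 beta = 0,
                                 sigma2 = NULL) {
  outcome_kind <- match.arg(outcome_kind)
  tiers <- rep(c("low", "medium", "high", "very_high"), times = c(3, 3, 3, 1))
  linear <- rep(c(1.1, 1.25, 1.5, 2), times = c(3, 3, 3, 1))
  if (is.null(intercept_outcome)) {
    intercept_outcome <- if (outcome_kind == "binary") log(0.29 / 0.71) else 0
  }
  if (is.null(sigma2)) {
    sigma2 <- if (outcome_kind == "continuous") 127.6056 else NA_real_
  }
  if (outcome_kind == "continuous" && (!is.finite(sigma2) || sigma2 <= 0)) {
    stop("sigma2 must be positive for continuous outcomes", call. = FALSE)
  }
  structure(
    list(
      outcome_kind      = outcome_kind,
      tiers             = tiers,
      treat_coefs       = log(linear),
      outcome_coefs     = if (outcome_kind == "binary") log(linear) else linear,
      intercept_treat   = intercept_treat,
      intercept_outcome = intercept_outcome,
      beta              = beta,
      sigma2            = sigma2
    ),
    class = "coefficient_set"
  )
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("Coefficient set (", x$outcome_kind, " outcome)\n", sep = "")
  cat("  treatment coefs:", paste(signif(x$treat_coefs, 4), collapse = " "), "\n")
  cat("  outcome coefs:  ", paste(signif(x$outcome_coefs, 4), collapse = " "), "\n")
  cat("  intercepts: treat =", signif(x$intercept_treat, 6),
      " outcome =", signif(x$intercept_outcome, 6), "\n")
  cat("  beta =", signif(x$beta, 7), "\n")
  if (x$outcome_kind == "continuous") cat("  sigma2 =", x$sigma2, "\n")
  invisible(x)
}
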