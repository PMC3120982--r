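expit <- stats::plogis

logit <- function(p) log(p / (1 - p))

# Run `expr` under a locally-seeded RNG stream; the caller's RNG state is
# restored afterwards. seed = NULL leaves the current stream untouched so that
# callers (e.g. the replicate engine) can supply one stream for a whole block.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Generate baseline covariates under a scenario
#'
#' Draws an `n x 10` covariate matrix whose columns follow the scenario's
#' marginal distributions: standard normal, equicorrelated normal (generated
#' through a Cholesky factor of the exchangeable correlation matrix), or
#' Bernoulli(0.5). Binary covariates occupy the leading columns.
#'
#' @param scenario A [covariate_scenario()] object or scenario name.
#' @param n Number of subjects (rows).
#' @param seed Optional integer seed; the draw is reproducible given the seed
#'   and the caller's RNG state is untouched. `NULL` uses the current stream.
#' @return Numeric matrix with columns `x1`..`x10`.
#' @export
generate_covariates <- function(scenario, n, seed = NULL) {
  scenario <- as_scenario(scenario)
  stopifnot(n >= 1)
  with_seed(seed, {
    p <- scenario$n_covariates
    nb <- scenario$n_binary
    X <- matrix(0, nrow = n, ncol = p)
    if (nb > 0) {
      X[, seq_len(nb)] <- stats::rbinom(n * nb, 1L, scenario$bernoulli_p)
    }
    nn <- p - nb
    if (nn > 0) {
      G <- matrix(stats::rnorm(n * nn), nrow = n, ncol = nn)
      if (scenario$correlation > 0 && nn > 1) {
        R <- matrix(scenario$correlation, nn, nn)
        diag(R) <- 1
        G <- G %*% chol(R)
      }
      X[, nb + seq_len(nn)] <- G
    }
    colnames(X) <- paste0("x", seq_len(p))
    X
  })
}

#' Assign treatment from the logistic exposure model
#'
#' Computes the treatment linear predictor
#' `lp = intercept_treat + X %*% treat_coefs` and draws `Z ~ Bernoulli(expit(lp))`.
#'
#' @param covariates `n x 10` covariate matrix.
#' @param coeffs A [default_coefficients()] object with a finite
#'   `intercept_treat` (see [calibrate_treatment_intercept()]).
#' @param seed Optional integer seed (see [generate_covariates()]).
#' @return List with `z` (integer 0/1 vector) and `lp_treat` (log-odds).
#' @export
assign_treatment <- function(covariates, coeffs, seed = NULL) {
  stopifnot(ncol(covariates) == length(coeffs$treat_coefs))
  if (!is.finite(coeffs$intercept_treat)) {
    stop("intercept_treat is not set; calibrate it first", call. = FALSE)
  }
  lp <- coeffs$intercept_treat + drop(covariates %*% coeffs$treat_coefs)
  z <- with_seed(seed, stats::rbinom(length(lp), 1L, expit(lp)))
  list(z = z, lp_treat = lp)
}

outcome_base_lp <- function(covariates, coeffs) {
  coeffs$intercept_outcome + drop(covariates %*% coeffs$outcome_coefs)
}

#' Simulate binary outcomes
#'
#' Draws `Y ~ Bernoulli(expit(intercept_outcome + beta * z + X %*% outcome_coefs))`.
#'
#' @inheritParams assign_treatment
#' @param z Treatment indicator aligned with `covariates` rows.
#' @return Integer 0/1 outcome vector.
#' @export
simulate_binary_outcomes <- function(covariates, z, coeffs, seed = NULL) {
  stopifnot(length(z) == nrow(covariates))
  p <- expit(outcome_base_lp(covariates, coeffs) + coeffs$beta * z)
  with_seed(seed, stats::rbinom(length(p), 1L, p))
}

#' Simulate continuous outcomes
#'
#' Draws `Y = intercept_outcome + beta * z + X %*% outcome_coefs + e`,
#' `e ~ N(0, sigma2)`. Because differences in means are collapsible, the ATT
#' equals `beta` exactly.
#'
#' @inheritParams simulate_binary_outcomes
#' @return Numeric outcome vector.
#' @export
simulate_continuous_outcomes <- function(covariates, z, coeffs, seed = NULL) {
  stopifnot(length(z) == nrow(covariates))
  if (!is.finite(coeffs$sigma2) || coeffs$sigma2 < 0) {
    stop("sigma2 must be a non-negative number", call. = FALSE)
  }
  mu <- outcome_base_lp(covariates, coeffs) + coeffs$beta * z
  with_seed(seed, mu + stats::rnorm(length(mu), sd = sqrt(coeffs$sigma2)))
}

#' Simulate one complete cohort
#'
#' Generates covariates, treatment and outcome for one replicate in a single
#' seeded stream.
#'
#' @inheritParams generate_covariates
#' @param coeffs Calibrated [default_coefficients()] object.
#' @return An object of class `simulated_cohort`: `covariates`, `z`, `y`,
#'   `lp_treat`, `lp_outcome_base` (outcome linear predictor excluding the
#'   treatment term) and `seed`.
#' @export
simulate_cohort <- function(scenario, coeffs, n = 10000, seed = NULL) {
  scenario <- as_scenario(scenario)
  with_seed(seed, {
    X <- generate_covariates(scenario, n)
    trt <- assign_treatment(X, coeffs)
    y <- if (coeffs$outcome_kind == "binary") {
      simulate_binary_outcomes(X, trt$z, coeffs)
    } else {
      simulate_continuous_outcomes(X, trt$z, coeffs)
    }
    structure(
      list(
        covariates      = X,
        z               = trt$z,
        y               = y,
        lp_treat        = trt$lp_treat,
        lp_outcome_base = outcome_base_lp(X, coeffs),
        seed            = if (is.null(seed)) NA_integer_ else as.integer(seed)
      ),
      class = "simulated_cohort"
    )
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(x$z), "subjects,",
      sum(x$z), "treated;", "outcome", class(x$y), "\n")
  invisible(x)
}

#' @export
as.data.frame.simulated_cohort <- function(x, ...) {
  out <- as.data.frame(x$covariates)
  out$z <- x$z
  out$y <- x$y
  out
}
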