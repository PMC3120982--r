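#' Fit the propensity-score model
#'
#' Maximum-likelihood logistic regression of treatment on the covariates
#' (main effects only), via [stats::glm()] with a tight convergence tolerance.
#' Returns the estimated propensity score and its logit; matching is done on
#' the logit because it is closer to normally distributed than the probability
#' itself.
#'
#' @param covariates Numeric matrix or data frame of baseline covariates.
#' @param z Binary treatment indicator (0/1), both groups non-empty.
#' @return Object of class `propensity_fit`: `coefficients`, `ps`, `logit_ps`,
#'   `converged`, `iterations`.
#' @export
fit_propensity <- function(covariates, z) {
  covariates <- as.matrix(covariates)
  z <- as.integer(z)
  if (length(unique(z)) < 2L) {
    stop("both treatment groups must be non-empty", call. = FALSE)
  }
  fit <- stats::glm.fit(cbind(`(Intercept)` = 1, covariates), z,
                        family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100))
  ps <- fit$fitted.values
  eps <- .Machine$double.eps
  if (!fit$converged || any(ps < eps) || any(ps > 1 - eps)) {
    bad <- names(which(abs(fit$coefficients[-1]) > 10))
    stop("propensity model did not converge cleanly",
         if (length(bad)) paste0(" (possible separation in: ",
                                 paste(bad, collapse = ", "), ")"),
         call. = FALSE)
  }
  structure(
    list(coefficients = fit$coefficients,
         ps = ps,
         logit_ps = log(ps / (1 - ps)),
         converged = fit$converged,
         iterations = fit$iter),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Propensity model:", length(x$coefficients) - 1, "covariates,",
      x$iterations, "IRLS iterations\n")
  cat("  logit PS range:", paste(signif(range(x$logit_ps), 4), collapse = " to "), "\n")
  invisible(x)
}

#' Caliper width from a gamma multiplier
#'
#' The caliper is `gamma` times the pooled standard deviation of the logit
#' propensity score, `sqrt((s2_treated + s2_control) / 2)`, with group sample
#' variances computed on the full unmatched sample.
#'
#' @param logit_ps Logit propensity scores for the full sample.
#' @param z Treatment indicator.
#' @param gamma Positive unitless multiplier (0.2 is the usual
#'   recommendation).
#' @return Caliper width in logit units, with attribute `sd_pooled`.
#' @export
caliper_width <- function(logit_ps, z, gamma) {
  stopifnot(gamma >= 0, length(logit_ps) == length(z))
  v1 <- stats::var(logit_ps[z == 1])
  v0 <- stats::var(logit_ps[z == 0])
  if (is.na(v1) || is.na(v0)) {
    stop("need at least 2 subjects per group to compute the pooled SD",
         call. = FALSE)
  }
  sd_pooled <- sqrt((v1 + v0) / 2)
  if (sd_pooled == 0) {
    warning("logit propensity score is degenerate; caliper width is 0")
  }
  structure(gamma * sd_pooled, sd_pooled = sd_pooled)
}

new_matched_sample <- function(pairs, gamma, width, sd_pooled, order_seed) {
  structure(
    list(pairs = pairs, gamma = gamma, caliper_width = as.numeric(width),
         sd_pooled = sd_pooled, order_seed = order_seed),
    class = "matched_sample"
  )
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf("Matched sample: %d pairs (gamma = %s, caliper width = %.4g)\n",
              nrow(x$pairs),
              if (is.na(x$gamma)) "explicit width" else format(x$gamma),
              x$caliper_width))
  invisible(x)
}

#' Greedy nearest-neighbor pair matching without replacement
#'
#' Treated subjects are processed in a random order determined by
#' `order_seed`; each is matched to the nearest not-yet-matched control whose
#' logit propensity score lies within the caliper. Unmatched treated subjects
#' are dropped; every subject appears in at most one pair. Exact distance ties
#' are broken toward the lower control row index.
#'
#' @inheritParams caliper_width
#' @param width Caliper width in logit units (an absolute distance, not a
#'   gamma multiplier; see [caliper_width()]).
#' @param order_seed Integer seed controlling the treated processing order;
#'   `NULL` draws the order from the current RNG stream.
#' @return Object of class `matched_sample`; `pairs` is a two-column integer
#'   matrix of row indices (`treated`, `control`).
#' @export
greedy_match <- function(logit_ps, z, width, order_seed = NULL) {
  stopifnot(width >= 0, length(logit_ps) == length(z))
  t_idx <- which(z == 1)
  c_idx <- which(z == 0)
  perm <- with_seed(order_seed, sample.int(length(t_idx)))
  t_idx <- t_idx[perm]

  ord <- order(logit_ps[c_idx])              # stable: ties by row index
  c_sorted <- c_idx[ord]
  pos <- greedy_match_cpp(logit_ps[t_idx], logit_ps[c_sorted],
                          as.numeric(width), as.integer(c_sorted))
  hit <- pos > 0L
  pairs <- cbind(treated = t_idx[hit], control = c_sorted[pos[hit]])
  new_matched_sample(pairs, NA_real_, width,
                     attr(width, "sd_pooled") %||% NA_real_, order_seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match one sample at a grid of gamma values
#'
#' Forms one matched sample per `gamma`, all with the same treated processing
#' order, so samples differ only through the caliper width. The default grid
#' is the 50-point sweep `seq(0.05, 2.50, by = 0.05)`.
#'
#' @inheritParams greedy_match
#' @param gammas Vector of positive gamma multipliers.
#' @return Named list of `matched_sample` objects (names are the gamma
#'   values); each carries `gamma`, `caliper_width` and `sd_pooled`.
#' @export
match_gamma_grid <- function(logit_ps, z, gammas = default_gamma_grid(),
                             order_seed = NULL) {
  stopifnot(length(gammas) >= 1, all(gammas > 0))
  # fix one processing order for all gammas
  n_t <- sum(z == 1)
  perm_seed <- with_seed(order_seed, sample.int(.Machine$integer.max, 1L))
  out <- lapply(gammas, function(g) {
    w <- caliper_width(logit_ps, z, g)
    m <- greedy_match(logit_ps, z, w, order_seed = perm_seed)
    m$gamma <- g
    m$order_seed <- order_seed
    m
  })
  names(out) <- format(gammas)
  out
}

#' The 50-point caliper sweep grid
#'
#' @return `seq(0.05, 2.50, by = 0.05)`.
#' @export
default_gamma_grid <- function() seq(0.05, 2.50, by = 0.05)

#' Export a matched sample as a data frame
#'
#' @param x A `matched_sample`.
#' @param logit_ps Optional logit propensity scores used to add per-pair
#'   score and distance columns.
#' @param ... Unused.
#' @return Data frame with `pair_id`, `treated_row`, `control_row` and, when
#'   `logit_ps` is supplied, `logit_ps_treated`, `logit_ps_control`,
#'   `distance`.
#' @export
as.data.frame.matched_sample <- function(x, logit_ps = NULL, ...) {
  out <- data.frame(pair_id = seq_len(nrow(x$pairs)),
                    treated_row = x$pairs[, "treated"],
                    control_row = x$pairs[, "control"])
  if (!is.null(logit_ps)) {
    out$logit_ps_treated <- logit_ps[out$treated_row]
    out$logit_ps_control <- logit_ps[out$control_row]
    out$distance <- abs(out$logit_ps_treated - out$logit_ps_control)
  }
  out
}
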