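# Naive O(nT * nC) greedy matcher used as an independent oracle: treated
# subjects in the given order, each matched to the nearest unused control
# within the caliper, exact distance ties to the lowest control row index.
brute_force_match <- function(logit_ps, z, width, t_order) {
  t_idx <- which(z == 1)[t_order]
  c_idx <- which(z == 0)
  used <- rep(FALSE, length(logit_ps))
  pairs <- matrix(0L, 0, 2)
  for (t in t_idx) {
    d <- abs(logit_ps[c_idx] - logit_ps[t])
    d[used[c_idx]] <- Inf
    elig <- which(d <= width)
    if (!length(elig)) next
    dmin <- min(d[elig])
    pick <- min(c_idx[elig][d[elig] == dmin])
    used[pick] <- TRUE
    pairs <- rbind(pairs, c(t, pick))
  }
  pairs
}

# Processing order used by greedy_match for a given order seed
treated_order_for_seed <- function(seed, n_treated) {
  set.seed(seed)
  sample.int(n_treated)
}

# Random small matching instance; odd draws use rounded (heavily tied) scores
random_match_instance <- function(n_range = 20:90, p_treat = 0.35,
                                  tied = FALSE) {
  repeat {
    n <- sample(n_range, 1)
    z <- stats::rbinom(n, 1, p_treat)
    if (sum(z) > 0 && sum(z == 0) > 0) break
  }
  lp <- stats::rnorm(n)
  if (tied) lp <- round(lp, 1)
  list(lp = lp, z = z)
}

# Coefficient set with all covariate effects removed (null confounding)
null_coefficients <- function(outcome_kind, beta = 0, sigma2 = NULL) {
  cf <- default_coefficients(outcome_kind)
  cf$treat_coefs[] <- 0
  cf$outcome_coefs[] <- 0
  cf$intercept_treat <- 0
  cf$beta <- beta
  if (!is.null(sigma2)) cf$sigma2 <- sigma2
  cf
}

# Unique scratch file cleaned up when the calling test completes
withr_local_file <- function(name, env = parent.frame()) {
  path <- tempfile(pattern = paste0(sub("\\..*$", "", name), "-"),
                   fileext = sub("^[^.]*", "", name))
  withr::defer(unlink(path), envir = env)
  path
}
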