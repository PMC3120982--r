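test_that("propensity fit matches closed-form logistic MLEs", {
  # single binary covariate, 2x2 counts: slope = log cross-product ratio
  x <- c(rep(1, 30), rep(0, 20), rep(1, 20), rep(0, 30))
  z <- c(rep(1, 50), rep(0, 50))
  fit <- fit_propensity(matrix(x, ncol = 1), z)
  expect_equal(unname(fit$coefficients[2]), log((30 * 30) / (20 * 20)),
               tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$logit_ps, log(fit$ps / (1 - fit$ps)))

  # intercept-only model: intercept is the logit of the treated fraction
  fit0 <- fit_propensity(matrix(nrow = 100, ncol = 0), rep(c(1, 0), c(30, 70)))
  expect_equal(unname(fit0$coefficients[1]), log(0.3 / 0.7), tolerance = 1e-8)
})

test_that("propensity fit recovers a null model and rejects degenerate input", {
  set.seed(31)
  X <- matrix(rnorm(2e4 * 3), ncol = 3)
  z <- rbinom(2e4, 1, 0.4)  # independent of X
  fit <- fit_propensity(X, z)
  expect_true(all(abs(fit$coefficients[-1]) < 4 / sqrt(2e4 * 0.24)))
  expect_error(fit_propensity(X, rep(1, 2e4)), "non-empty")

  # perfectly separating covariate
  xs <- matrix(c(rep(0, 50), rep(1, 50)), ncol = 1)
  suppressWarnings(
    expect_error(fit_propensity(xs, c(rep(0, 50), rep(1, 50))), "converge")
  )
})

test_that("caliper width is gamma times the pooled SD of the logit PS", {
  set.seed(32)
  lp <- rnorm(400); z <- rep(0:1, 200)
  w <- caliper_width(lp, z, 0.2)
  expect_equal(as.numeric(w),
               0.2 * sqrt((var(lp[z == 1]) + var(lp[z == 0])) / 2))
  expect_equal(attr(w, "sd_pooled"),
               sqrt((var(lp[z == 1]) + var(lp[z == 0])) / 2))
  # var_T = 2, var_C = 0 -> pooled SD 1
  lp2 <- c(sqrt(2) * scale(rnorm(50))[, 1], rep(0.5, 50))
  z2 <- rep(1:0, each = 50)
  expect_equal(as.numeric(caliper_width(lp2, z2, 1)), 1, tolerance = 1e-10)
  expect_equal(as.numeric(caliper_width(lp, z, 0)), 0)
  expect_warning(caliper_width(rep(1, 10), rep(0:1, 5), 0.2), "degenerate")
})

test_that("greedy matching honours the caliper and nearest-neighbour rule", {
  # unique nearest control inside the caliper
  lp <- c(0.0, 0.05, 0.3); z <- c(1, 0, 0)
  m <- greedy_match(lp, z, 0.1, order_seed = 1)
  expect_equal(unname(m$pairs), cbind(1L, 2L))
  # no control inside the caliper
  m2 <- greedy_match(c(0, 0.5), c(1, 0), 0.1, order_seed = 1)
  expect_equal(nrow(m2$pairs), 0)
  # each subject used at most once
  lp3 <- c(0, 0.01, 0.02); z3 <- c(1, 1, 0)
  m3 <- greedy_match(lp3, z3, 1, order_seed = 1)
  expect_equal(nrow(m3$pairs), 1)
})

test_that("greedy matcher equals the brute-force oracle on random instances", {
  set.seed(33)
  for (i in 1:60) {
    inst <- random_match_instance(tied = i %% 2 == 0)
    w <- runif(1, 0, 1.5)
    seed <- sample.int(1e6, 1)
    m <- greedy_match(inst$lp, inst$z, w, order_seed = seed)
    ord <- treated_order_for_seed(seed, sum(inst$z == 1))
    bf <- brute_force_match(inst$lp, inst$z, w, ord)
    expect_identical(unname(m$pairs), unname(bf))
  }
})

test_that("matched samples always satisfy their invariants", {
  set.seed(34)
  for (i in 1:25) {
    inst <- random_match_instance()
    w <- runif(1, 0, 2)
    m <- greedy_match(inst$lp, inst$z, w, order_seed = i)
    idx <- as.vector(m$pairs)
    expect_false(any(duplicated(idx)))        # without replacement
    expect_true(all(inst$z[m$pairs[, "treated"]] == 1))
    expect_true(all(inst$z[m$pairs[, "control"]] == 0))
    d <- abs(inst$lp[m$pairs[, "treated"]] - inst$lp[m$pairs[, "control"]])
    expect_true(all(d <= w + 1e-12))          # within caliper
  }
})

test_that("matching is invariant to permuting control rows", {
  set.seed(35)
  inst <- random_match_instance(n_range = 60:80)
  w <- 0.4
  m1 <- greedy_match(inst$lp, inst$z, w, order_seed = 7)
  # permute only the control rows, keeping treated rows in place
  perm <- seq_along(inst$lp)
  ctrl <- which(inst$z == 0)
  perm[ctrl] <- sample(ctrl)
  lp2 <- inst$lp; lp2[perm] <- inst$lp
  z2 <- inst$z; z2[perm] <- inst$z
  m2 <- greedy_match(lp2, z2, w, order_seed = 7)
  # same treated subjects matched to the same control *scores*
  expect_identical(m1$pairs[, "treated"], m2$pairs[, "treated"])
  expect_equal(sort(inst$lp[m1$pairs[, "control"]]),
               sort(lp2[m2$pairs[, "control"]]))
})

test_that("gamma grid produces one sample per gamma with a shared order", {
  set.seed(36)
  inst <- random_match_instance(n_range = 100:140)
  grid <- default_gamma_grid()
  ms <- match_gamma_grid(inst$lp, inst$z, grid, order_seed = 9)
  expect_length(ms, 50)
  expect_equal(vapply(ms, function(m) m$gamma, numeric(1)),
               grid, ignore_attr = TRUE)

  # pair count is monotone non-decreasing in gamma
  counts <- vapply(ms, function(m) nrow(m$pairs), integer(1))
  expect_true(all(diff(counts) >= 0))

  # wide-open caliper matches every treated subject (controls outnumber them)
  n_t <- sum(inst$z == 1); n_c <- sum(inst$z == 0)
  big <- match_gamma_grid(inst$lp, inst$z, 1e6, order_seed = 9)[[1]]
  expect_equal(nrow(big$pairs), min(n_t, n_c))

  # each grid entry equals a standalone greedy run with the shared order seed
  derived <- { set.seed(9); sample.int(.Machine$integer.max, 1) }
  for (g in c(0.1, 0.5, 2.5)) {
    w <- caliper_width(inst$lp, inst$z, g)
    solo <- greedy_match(inst$lp, inst$z, w, order_seed = derived)
    expect_identical(ms[[which(grid == g)]]$pairs, solo$pairs)
  }

  # mean within-pair distance grows (weakly) with gamma
  mean_d <- vapply(ms, function(m) {
    if (nrow(m$pairs) == 0) return(0)
    mean(abs(inst$lp[m$pairs[, "treated"]] - inst$lp[m$pairs[, "control"]]))
  }, numeric(1))
  expect_true(mean(diff(mean_d) >= -1e-12) > 0.9)  # near-monotone trend
})

test_that("matched samples export pair-level data frames", {
  lp <- c(0.0, 0.05, 0.3, -0.2); z <- c(1, 0, 0, 1)
  m <- greedy_match(lp, z, 0.3, order_seed = 2)
  df <- as.data.frame(m, logit_ps = lp)
  expect_named(df, c("pair_id", "treated_row", "control_row",
                     "logit_ps_treated", "logit_ps_control", "distance"))
  expect_equal(df$distance,
               abs(lp[df$treated_row] - lp[df$control_row]))
})
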