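fake_match <- function(n_pairs) {
  # pairs over rows 1..n (treated) and n+1..2n (controls)
  structure(list(pairs = cbind(treated = seq_len(n_pairs),
                               control = n_pairs + seq_len(n_pairs)),
                 gamma = NA_real_, caliper_width = Inf,
                 sd_pooled = NA_real_, order_seed = NULL),
            class = "matched_sample")
}

test_that("pair tables partition matched pairs by outcome pattern", {
  m <- fake_match(4)
  y <- c(1, 1, 0, 0, 1, 0, 1, 0)  # (1,1) (1,0) (0,1) (0,0)
  tab <- pair_table(m, y)
  expect_equal(unclass(tab)[c("a", "b", "c", "d", "n")],
               list(a = 1L, b = 1L, c = 1L, d = 1L, n = 4L))

  y0 <- rep(0, 8)
  tab0 <- pair_table(m, y0)
  expect_equal(c(tab0$a, tab0$b, tab0$c, tab0$d), c(0, 0, 0, 4))
  expect_equal(tab0$n, 4)

  set.seed(41)
  yr <- rbinom(8, 1, 0.5)
  tr <- pair_table(m, yr)
  expect_equal(tr$a + tr$b + tr$c + tr$d, tr$n)
  expect_error(pair_table(m, runif(8)), "binary")
})

test_that("matched risk difference uses the correlated-proportions variance", {
  tab <- structure(list(a = 10L, b = 25L, c = 5L, d = 60L, n = 100L),
                   class = "pair_table")
  est <- matched_risk_difference(tab)
  expect_equal(est$estimate, 0.20)
  expect_equal(est$se^2, (30 - 400 / 100) / 1e4)  # 0.0026
  expect_equal(est$se, 0.0510, tolerance = 1e-3)
  expect_equal(est$ci_low, 0.20 - 1.959964 * est$se)
  expect_equal(est$ci_high, 0.20 + 1.959964 * est$se)
  expect_equal(est$n_pairs, 100L)

  # b = c gives a zero estimate
  tabz <- structure(list(a = 3L, b = 7L, c = 7L, d = 3L, n = 20L),
                    class = "pair_table")
  expect_equal(matched_risk_difference(tabz)$estimate, 0)
})

test_that("risk difference equals the difference of marginal proportions", {
  set.seed(42)
  for (i in 1:50) {
    counts <- as.vector(stats::rmultinom(1, sample(10:500, 1), runif(4)))
    tab <- structure(list(a = counts[1], b = counts[2], c = counts[3],
                          d = counts[4], n = sum(counts)),
                     class = "pair_table")
    est <- matched_risk_difference(tab)
    expect_equal(est$estimate,
                 (tab$a + tab$b) / tab$n - (tab$a + tab$c) / tab$n)
    expect_gte(est$se^2, 0)
    expect_true(est$estimate >= -1 && est$estimate <= 1)
    expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)
  }
})

test_that("McNemar test depends only on the discordant counts", {
  tab <- function(a, b, c, d)
    structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
              class = "pair_table")
  expect_equal(mcnemar_p(tab(0, 10, 10, 0)), 1)
  expect_equal(mcnemar_p(tab(5, 15, 5, 5)),
               pchisq(5, 1, lower.tail = FALSE))  # (15-5)^2/20 = 5
  expect_equal(mcnemar_p(tab(5, 15, 5, 5)), 0.02535, tolerance = 1e-3)
  expect_equal(mcnemar_p(tab(50, 0, 0, 50)), 1)  # no discordant pairs
  # invariant to a and d
  expect_equal(mcnemar_p(tab(0, 12, 4, 0)), mcnemar_p(tab(99, 12, 4, 1)))
})

test_that("matched mean difference reproduces the one-sample t on differences", {
  m <- fake_match(3)
  y <- c(2, 3, 4, 1, 1, 1)  # differences 1, 2, 3
  est <- matched_mean_difference(m, y)
  expect_equal(est$estimate, 2)
  expect_equal(est$se, 1 / sqrt(3))

  set.seed(43)
  n <- 40
  m2 <- fake_match(n)
  y2 <- rnorm(2 * n)
  est2 <- matched_mean_difference(m2, y2)
  ref <- t.test(y2[1:n] - y2[n + 1:n])
  expect_equal(est2$estimate, unname(ref$estimate))
  expect_equal(est2$p_value, ref$p.value)
  expect_equal(c(est2$ci_low, est2$ci_high), as.vector(ref$conf.int))

  # identical outcomes within every pair
  yc <- c(1:3, 1:3)
  estc <- matched_mean_difference(fake_match(3), yc)
  expect_equal(estc$estimate, 0)
  expect_equal(estc$p_value, 1)
  expect_error(matched_mean_difference(fake_match(1), c(1, 2)), "2 pairs")
})

test_that("crude effects are unadjusted group differences", {
  z <- rep(c(1, 0), c(100, 300))
  y <- c(rep(1, 40), rep(0, 60), rep(1, 90), rep(0, 210))  # 0.4 vs 0.3
  est <- crude_effect(z, y, "risk_difference")
  expect_equal(est$estimate, 0.1)
  expect_equal(est$se, sqrt(0.4 * 0.6 / 100 + 0.3 * 0.7 / 300))

  set.seed(44)
  yc <- rnorm(400, mean = z)
  estc <- crude_effect(z, yc, "mean_difference")
  ref <- t.test(yc[z == 1], yc[z == 0])
  expect_equal(estc$estimate, unname(diff(rev(ref$estimate))))
  expect_equal(estc$p_value, ref$p.value)
  expect_equal(crude_effect(z, rep(2, 400), "mean_difference")$estimate, 0)
})

test_that("crude and matched estimators agree without confounding", {
  # null confounding, noiseless additive effect: both recover beta exactly
  cf <- null_coefficients("continuous", beta = 1.5, sigma2 = 1e-4)
  set.seed(45)
  cohort <- simulate_cohort("independent_normal", cf, n = 4000)
  m <- greedy_match(rep(0, 4000) + rnorm(4000, sd = 1e-6), cohort$z, 1,
                    order_seed = 1)
  matched <- matched_mean_difference(m, cohort$y)
  crude <- crude_effect(cohort$z, cohort$y, "mean_difference")
  expect_equal(matched$estimate, 1.5, tolerance = 0.01)
  expect_equal(crude$estimate, 1.5, tolerance = 0.01)
})

test_that("standardized differences follow the pooled-SD definition", {
  z <- rep(1:0, each = 100)
  x <- c(rnorm(100, 1, 1), rnorm(100, 0, 1))
  sdiff <- standardized_difference(x, z, "continuous")
  expect_equal(sdiff, abs(mean(x[1:100]) - mean(x[101:200])) /
                 sqrt((var(x[1:100]) + var(x[101:200])) / 2))

  # exact closed forms
  x2 <- c(rep(c(0, 2), 50), rep(c(-1, 1), 50))  # means 1 and 0
  expect_equal(standardized_difference(x2 * 0 + c(rep(1, 100), rep(0, 100)) +
                                         rep(0, 200), z, "continuous"),
               standardized_difference(c(rep(1, 100), rep(0, 100)), z,
                                       "continuous"))
  expect_equal(standardized_difference(rep(1, 200), z, "binary"), 0)

  # binary proportions 0.476 vs 0.328 give about 0.31
  p <- c(0.476, 0.328)
  num <- p[1] - p[2]
  den <- sqrt((p[1] * (1 - p[1]) + p[2] * (1 - p[2])) / 2)
  xb <- c(rep(1, 476), rep(0, 524), rep(1, 328), rep(0, 672))
  zb <- rep(1:0, each = 1000)
  expect_equal(standardized_difference(xb, zb, "binary"), num / den)
  expect_equal(round(standardized_difference(xb, zb, "binary"), 2), 0.31)

  # invariant to affine rescaling of a continuous variable
  expect_equal(standardized_difference(3 * x - 7, z, "continuous"), sdiff)
  # reported as an absolute value
  expect_equal(standardized_difference(-x, z, "continuous"), sdiff)
})
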