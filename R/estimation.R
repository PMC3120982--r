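Z975 <- 1.959964

new_effect_estimate <- function(estimand, estimate, se, ci_low, ci_high,
                                p_value, n_pairs) {
  structure(
    list(estimand = estimand, estimate = estimate, se = se,
         ci_low = ci_low, ci_high = ci_high, p_value = p_value,
         n_pairs = n_pairs),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4g (SE %.4g, 95%% CI %.4g to %.4g, p = %.4g, n = %d)\n",
              gsub("_", " ", x$estimand), x$estimate, x$se,
              x$ci_low, x$ci_high, x$p_value, x$n_pairs))
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(estimand = x$estimand, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
             n_pairs = x$n_pairs)
}

#' Cross-classify matched pairs by binary outcomes
#'
#' Counts the four pair types of a matched binary-outcome sample: `a` pairs
#' where both members have the event, `b` where only the treated member does,
#' `c` where only the control does, `d` where neither does.
#'
#' @param matched A [greedy_match()] result.
#' @param y Binary outcome vector for the full sample.
#' @return Object of class `pair_table` with fields `a`, `b`, `c`, `d`, `n`.
#' @export
pair_table <- function(matched, y) {
  yt <- y[matched$pairs[, "treated"]]
  yc <- y[matched$pairs[, "control"]]
  if (!all(yt %in% 0:1) || !all(yc %in% 0:1)) {
    stop("pair_table requires binary 0/1 outcomes", call. = FALSE)
  }
  structure(
    list(a = sum(yt == 1 & yc == 1), b = sum(yt == 1 & yc == 0),
         c = sum(yt == 0 & yc == 1), d = sum(yt == 0 & yc == 0),
         n = length(yt)),
    class = "pair_table"
  )
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("Pair table (n = %d): a = %d, b = %d, c = %d, d = %d\n",
              x$n, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Matched-pair risk difference with McNemar-based inference
#'
#' Estimates the risk difference between treated and control members of the
#' matched pairs as `(b - c)/n` with variance
#' `(b + c - (b - c)^2/n) / n^2`, the standard correlated-proportions form.
#' The 95% CI is Wald (`z = 1.959964`); the p-value is McNemar's test
#' ([mcnemar_p()]).
#'
#' @param tab A [pair_table()].
#' @return An `effect_estimate` with estimand `"risk_difference"`.
#' @export
matched_risk_difference <- function(tab) {
  if (tab$n < 1) stop("risk difference undefined for 0 pairs", call. = FALSE)
  n <- tab$n
  est <- (tab$b - tab$c) / n
  v <- (tab$b + tab$c - (tab$b - tab$c)^2 / n) / n^2
  se <- sqrt(v)
  new_effect_estimate("risk_difference", est, se,
                      est - Z975 * se, est + Z975 * se,
                      mcnemar_p(tab), n)
}

#' McNemar's test for correlated proportions
#'
#' Chi-square statistic `(b - c)^2 / (b + c)` on 1 df, without continuity
#' correction; depends only on the discordant pair counts. When there are no
#' discordant pairs the p-value is 1.
#'
#' @param tab A [pair_table()].
#' @return Two-sided p-value.
#' @export
mcnemar_p <- function(tab) {
  if (tab$n < 1) stop("McNemar test undefined for 0 pairs", call. = FALSE)
  disc <- tab$b + tab$c
  if (disc == 0) return(1)
  stats::pchisq((tab$b - tab$c)^2 / disc, df = 1, lower.tail = FALSE)
}

#' Matched-pair mean difference with paired-t inference
#'
#' The treatment effect is the mean of the within-pair differences
#' `d_i = y_treated_i - y_control_i`; its standard error is `sd(d)/sqrt(n)`,
#' with CI and p-value from the t distribution on `n - 1` degrees of freedom
#' (one-sample t test of the differences against zero).
#'
#' @param matched A [greedy_match()] result.
#' @param y Continuous outcome vector for the full sample.
#' @return An `effect_estimate` with estimand `"mean_difference"`.
#' @export
matched_mean_difference <- function(matched, y) {
  d <- y[matched$pairs[, "treated"]] - y[matched$pairs[, "control"]]
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs for a paired t estimate", call. = FALSE)
  est <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  if (se == 0) {
    return(new_effect_estimate("mean_difference", est, 0, est, est,
                               if (est == 0) 1 else 0, n))
  }
  tq <- stats::qt(0.975, df = n - 1)
  p <- 2 * stats::pt(abs(est / se), df = n - 1, lower.tail = FALSE)
  new_effect_estimate("mean_difference", est, se, est - tq * se,
                      est + tq * se, p, n)
}

#' Crude (unadjusted) treatment effect in the full sample
#'
#' Difference in outcome means (or event proportions) between all treated and
#' all untreated subjects, with the usual two-sample variance: binomial for
#' risk differences, Welch for mean differences.
#'
#' @param z Treatment indicator.
#' @param y Outcome vector.
#' @param estimand `"risk_difference"` or `"mean_difference"`.
#' @return An `effect_estimate`; `n_pairs` records `min(n1, n0)`.
#' @export
crude_effect <- function(z, y, estimand = c("risk_difference",
                                            "mean_difference")) {
  estimand <- match.arg(estimand)
  y1 <- y[z == 1]; y0 <- y[z == 0]
  n1 <- length(y1); n0 <- length(y0)
  stopifnot(n1 >= 2, n0 >= 2)
  est <- mean(y1) - mean(y0)
  if (estimand == "risk_difference") {
    p1 <- mean(y1); p0 <- mean(y0)
    se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
    p <- if (se == 0) as.numeric(est != 0)
         else 2 * stats::pnorm(abs(est / se), lower.tail = FALSE)
    return(new_effect_estimate(estimand, est, se, est - Z975 * se,
                               est + Z975 * se, p, min(n1, n0)))
  }
  v1 <- stats::var(y1) / n1; v0 <- stats::var(y0) / n0
  se <- sqrt(v1 + v0)
  df <- (v1 + v0)^2 / (v1^2 / (n1 - 1) + v0^2 / (n0 - 1))
  tq <- stats::qt(0.975, df)
  p <- if (se == 0) as.numeric(est != 0)
       else 2 * stats::pt(abs(est / se), df, lower.tail = FALSE)
  new_effect_estimate(estimand, est, se, est - tq * se, est + tq * se,
                      p, min(n1, n0))
}

#' Standardized difference balance diagnostic
#'
#' Absolute between-group difference in means (continuous) or proportions
#' (binary), scaled by the pooled standard deviation:
#' `|m1 - m0| / sqrt((s1^2 + s0^2)/2)` for continuous variables and
#' `|p1 - p0| / sqrt((p1(1-p1) + p0(1-p0))/2)` for binary ones. Unlike a test
#' statistic it does not grow with sample size, which makes it the standard
#' balance diagnostic for matched cohorts.
#'
#' @param values Covariate vector.
#' @param z Treatment indicator aligned with `values`.
#' @param kind `"continuous"` or `"binary"`.
#' @return Absolute standardized difference (unitless); `NaN` when both
#'   groups are degenerate.
#' @export
standardized_difference <- function(values, z,
                                    kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  v1 <- values[z == 1]; v0 <- values[z == 0]
  if (kind == "binary") {
    p1 <- mean(v1); p0 <- mean(v0)
    denom <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
    num <- p1 - p0
  } else {
    denom <- sqrt((stats::var(v1) + stats::var(v0)) / 2)
    num <- mean(v1) - mean(v0)
  }
  if (denom == 0) return(if (num == 0) 0 else NaN)
  abs(num) / denom
}
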