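#' Declare the layout of a cohort table
#'
#' @param treatment_column Name of the binary (0/1) treatment column.
#' @param outcome_column Name of the outcome column.
#' @param outcome_kind `"binary"` or `"continuous"`.
#' @param binary_covariates,continuous_covariates Names of the covariate
#'   columns by kind. Binary covariates must be pre-coded 0/1 (no automatic
#'   dummy expansion).
#' @return Object of class `cohort_schema`.
#' @export
cohort_schema <- function(treatment_column, outcome_column,
                          outcome_kind = c("binary", "continuous"),
                          binary_covariates = character(),
                          continuous_covariates = character()) {
  outcome_kind <- match.arg(outcome_kind)
  if (length(binary_covariates) + length(continuous_covariates) == 0) {
    stop("at least one covariate column is required", call. = FALSE)
  }
  structure(
    list(treatment_column = treatment_column,
         outcome_column = outcome_column,
         outcome_kind = outcome_kind,
         binary_covariates = binary_covariates,
         continuous_covariates = continuous_covariates),
    class = "cohort_schema"
  )
}

schema_columns <- function(schema) {
  c(schema$treatment_column, schema$outcome_column,
    schema$binary_covariates, schema$continuous_covariates)
}

#' Read and validate a cohort CSV
#'
#' Comma-separated, header row, `.` decimal, empty fields as missing. Rows
#' with missing values in any schema column are dropped (complete-case
#' filtering) with the exclusion count reported on stderr.
#'
#' @param path CSV file path.
#' @param schema A [cohort_schema()].
#' @return Validated data frame restricted to complete cases.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  validate_cohort(df, schema)
}

#' Validate an in-memory cohort against a schema
#'
#' @inheritParams read_cohort
#' @param df Cohort data frame.
#' @return The complete-case filtered data frame.
#' @export
validate_cohort <- function(df, schema) {
  cols <- schema_columns(schema)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(df[cols])
  if (any(!keep)) {
    message(sum(!keep), " row(s) excluded for missing values in schema columns")
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  z <- df[[schema$treatment_column]]
  if (!all(z %in% 0:1)) {
    stop("treatment column '", schema$treatment_column,
         "' must contain only 0/1", call. = FALSE)
  }
  if (length(unique(z)) < 2) {
    stop("one treatment arm is empty", call. = FALSE)
  }
  for (col in schema$binary_covariates) {
    if (!all(df[[col]] %in% 0:1)) {
      stop("binary covariate '", col, "' contains values other than 0/1",
           call. = FALSE)
    }
  }
  if (schema$outcome_kind == "binary" &&
      !all(df[[schema$outcome_column]] %in% 0:1)) {
    stop("binary outcome column '", schema$outcome_column,
         "' must contain only 0/1", call. = FALSE)
  }
  df
}

#' Write a cohort CSV
#'
#' Deterministic plain CSV (comma separator, header, no row names, `.`
#' decimal, missing as empty), so identical tables produce identical bytes.
#'
#' @param df Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- synthetic heart-failure-like fixture ---------------------------------

fixture_continuous <- function() {
  # name, mean, sd, lower truncation, decimals
  list(
    age         = c(77,   10.5, 20,  0),
    sbp         = c(150,  32,   60,  0),
    heart_rate  = c(92,   24,   30,  0),
    resp_rate   = c(24.5, 7,    8,   0),
    hemoglobin  = c(124,  20,   40,  0),
    wbc         = c(9.8,  4,    1,   1),
    sodium      = c(138.5, 4.3, 110, 0),
    potassium   = c(4.25, 0.62, 2,   1),
    glucose     = c(9.2,  4.8,  2,   1),
    bun         = c(9.5,  5.5,  1,   1),
    creatinine  = c(117,  55,   30,  0)
  )
}

fixture_binary <- function() {
  c(female = 0.50, neck_vein_distension = 0.551, s3 = 0.099, s4 = 0.038,
    rales = 0.104, pulmonary_edema = 0.514, cardiomegaly = 0.359,
    diabetes = 0.351, cva_tia = 0.160, previous_mi = 0.368, afib = 0.290,
    pvd = 0.130, copd = 0.166, dementia = 0.067, cirrhosis = 0.007,
    cancer = 0.112, lbbb = 0.148)
}

# log-odds per standardized continuous covariate / per binary indicator
fixture_treat_coefs <- c(
  age = -0.25, sbp = 0.13, heart_rate = -0.15, resp_rate = -0.10,
  previous_mi = 0.60, copd = -0.85, dementia = -0.55, afib = -0.25,
  diabetes = 0.20, pulmonary_edema = 0.20, cancer = -0.20, cirrhosis = -1.0
)

fixture_outcome_coefs <- c(
  age = 0.50, sbp = -0.30, heart_rate = 0.10, resp_rate = 0.15,
  hemoglobin = -0.15, sodium = -0.25, bun = 0.40, creatinine = 0.20,
  previous_mi = 0.20, copd = 0.30, dementia = 0.70, cancer = 0.60,
  cirrhosis = 0.80, pvd = 0.20
)

#' Schema of the synthetic heart-failure cohort fixture
#'
#' @return The [cohort_schema()] matching [generate_fixture()] output:
#'   treatment `treated`, binary outcome `death_1yr`, 28 covariates.
#' @export
fixture_schema <- function() {
  cohort_schema(
    treatment_column = "treated",
    outcome_column = "death_1yr",
    outcome_kind = "binary",
    binary_covariates = names(fixture_binary()),
    continuous_covariates = names(fixture_continuous())
  )
}

#' Generate a synthetic heart-failure-like cohort
#'
#' Emulates the broad shape of a hospital heart-failure discharge cohort in
#' which the exposure is a beta-blocker prescription and the outcome is death
#' within one year: 28 mixed binary/continuous baseline covariates with
#' realistic marginal prevalences, a treatment prevalence targeted at 0.273
#' and a marginal one-year death rate targeted at 0.277, with confounding
#' induced through covariates shared by the treatment and outcome models
#' (age, previous MI, COPD, dementia, vitals). The treatment itself is
#' protective (conditional odds ratio 0.75). This is a synthetic stand-in for
#' demonstration and testing; it reproduces marginal structure, not any real
#' registry.
#'
#' Intercepts are solved on the drawn covariate sample, so the realised
#' treated fraction and event rate are binomial draws around the targets.
#'
#' @param n Number of subjects (default 7613).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param treated_fraction,event_rate Marginal targets.
#' @return Data frame (`treated`, `death_1yr`, covariates); the matching
#'   schema is available from [fixture_schema()].
#' @export
generate_fixture <- function(n = 7613, seed = 20260920,
                             treated_fraction = 0.273, event_rate = 0.277) {
  with_seed(seed, {
    cont <- fixture_continuous()
    df <- data.frame(row.names = seq_len(n))
    zscores <- list()
    for (nm in names(cont)) {
      p <- cont[[nm]]
      x <- pmax(stats::rnorm(n, p[1], p[2]), p[3])
      df[[nm]] <- round(x, p[4])
      zscores[[nm]] <- (df[[nm]] - p[1]) / p[2]
    }
    for (nm in names(fixture_binary())) {
      df[[nm]] <- stats::rbinom(n, 1L, fixture_binary()[[nm]])
    }

    lp_part <- function(coefs) {
      lp <- numeric(n)
      for (nm in names(coefs)) {
        v <- if (nm %in% names(zscores)) zscores[[nm]] else df[[nm]]
        lp <- lp + coefs[[nm]] * v
      }
      lp
    }

    lp_t <- lp_part(fixture_treat_coefs)
    a0t <- stats::uniroot(function(a) mean(expit(a + lp_t)) - treated_fraction,
                          c(-15, 15), tol = 1e-10)$root
    treated <- stats::rbinom(n, 1L, expit(a0t + lp_t))

    lp_o <- lp_part(fixture_outcome_coefs) + log(0.75) * treated
    a0o <- stats::uniroot(function(a) mean(expit(a + lp_o)) - event_rate,
                          c(-15, 15), tol = 1e-10)$root
    death <- stats::rbinom(n, 1L, expit(a0o + lp_o))

    out <- cbind(data.frame(treated = treated, death_1yr = death), df)
    rownames(out) <- NULL
    out
  })
}

# ---- gamma sweep on a cohort ----------------------------------------------

#' Sweep caliper widths over a cohort
#'
#' The applied counterpart of the simulation study: fit the propensity model
#' on the cohort, match at every gamma in the grid (logit-scale calipers,
#' shared treated processing order), and report the matched effect estimate
#' and covariate balance at each width.
#'
#' @param cohort Cohort data frame (already validated, or see
#'   [read_cohort()]).
#' @param schema A [cohort_schema()].
#' @param gammas Gamma grid (default [default_gamma_grid()]).
#' @param seed Integer seed for the treated processing order.
#' @return Object of class `sweep_report`: `estimates` (one row per gamma:
#'   `gamma`, `n_pairs`, `estimate`, `se`, `ci_low`, `ci_high`, `p_value`),
#'   `balance` (long data frame of absolute standardized differences per
#'   covariate: `gamma = NA` rows are the unmatched cohort), and the
#'   `propensity_fit`.
#' @export
apply_sweep <- function(cohort, schema, gammas = default_gamma_grid(),
                        seed = 1L) {
  cohort <- validate_cohort(cohort, schema)
  covs <- c(schema$binary_covariates, schema$continuous_covariates)
  kinds <- c(rep("binary", length(schema$binary_covariates)),
             rep("continuous", length(schema$continuous_covariates)))
  X <- as.matrix(cohort[covs])
  z <- cohort[[schema$treatment_column]]
  y <- cohort[[schema$outcome_column]]

  fit <- fit_propensity(X, z)
  matches <- match_gamma_grid(fit$logit_ps, z, gammas, order_seed = seed)

  est_rows <- lapply(matches, function(m) {
    if (nrow(m$pairs) == 0) {
      return(data.frame(gamma = m$gamma, n_pairs = 0L, estimate = NA_real_,
                        se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_))
    }
    e <- if (schema$outcome_kind == "binary") {
      matched_risk_difference(pair_table(m, y))
    } else {
      matched_mean_difference(m, y)
    }
    data.frame(gamma = m$gamma, n_pairs = e$n_pairs, estimate = e$estimate,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               p_value = e$p_value)
  })

  bal_for <- function(rows_t, rows_c, gamma) {
    sd_abs <- vapply(seq_along(covs), function(j) {
      standardized_difference(c(X[rows_t, j], X[rows_c, j]),
                              c(rep(1L, length(rows_t)), rep(0L, length(rows_c))),
                              kinds[j])
    }, numeric(1))
    data.frame(gamma = gamma, covariate = covs, kind = kinds,
               std_difference = sd_abs)
  }
  balance <- rbind(
    bal_for(which(z == 1), which(z == 0), NA_real_),
    do.call(rbind, lapply(matches, function(m) {
      if (nrow(m$pairs) == 0) return(NULL)
      bal_for(m$pairs[, "treated"], m$pairs[, "control"], m$gamma)
    }))
  )
  rownames(balance) <- NULL

  structure(
    list(estimates = do.call(rbind, c(est_rows, make.row.names = FALSE)),
         balance = balance, fit = fit,
         outcome_kind = schema$outcome_kind, seed = seed),
    class = "sweep_report"
  )
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("Caliper sweep over", nrow(x$estimates), "gamma values\n")
  est <- x$estimates
  show <- est[est$gamma %in% c(0.05, 0.1, 0.2, 0.5, 1, 2, 2.5) |
                seq_len(nrow(est)) %in% c(1, nrow(est)), ]
  print(format(show, digits = 4), row.names = FALSE)
  invisible(x)
}

# ---- study configuration files --------------------------------------------

#' Read a study specification from a YAML or JSON config file
#'
#' Recognised fields: `scenario`, `outcome_kind`, `true_effect`,
#' `n_subjects`, `n_replicates`, `gammas` (vector) or
#' `gamma_min`/`gamma_max`/`gamma_step`, `master_seed`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [study_spec()].
#' @export
read_study_spec <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  gammas <- if (!is.null(cfg$gammas)) {
    as.numeric(cfg$gammas)
  } else if (!is.null(cfg$gamma_min)) {
    seq(cfg$gamma_min, cfg$gamma_max, by = cfg$gamma_step %||% 0.05)
  } else {
    default_gamma_grid()
  }
  study_spec(
    scenario = cfg$scenario %||% "independent_normal",
    outcome_kind = cfg$outcome_kind %||% "binary",
    true_effect = cfg$true_effect %||% 0,
    n_subjects = cfg$n_subjects %||% 10000,
    n_replicates = cfg$n_replicates %||% 250,
    gammas = gammas,
    master_seed = cfg$master_seed %||% 1L
  )
}

#' Write a tidy metric table CSV
#'
#' @param table A `metric_table` from [run_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}
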