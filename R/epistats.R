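#' Sex-specific anemia flag
#'
#' Hemoglobin below 120 g/l for adult males or below 110 g/l for adult
#' (non-pregnant) females; both thresholds strict.
#'
#' @param hb hemoglobin in g/l (> 0).
#' @param sex `"male"` or `"female"` (vectorized).
#' @return Logical vector.
#' @export
anemia_flag <- function(hb, sex) {
  if (any(hb <= 0)) stop("hb must be positive")
  sex <- as.character(sex)
  bad <- !sex %in% c("male", "female")
  if (any(bad)) stop("unknown sex category: ", paste(unique(sex[bad]), collapse = ", "))
  ifelse(sex == "male", hb < 120, hb < 110)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes (`0 <= k <= n`).
#' @param n number of trials (`>= 1`).
#' @param conf confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`, both within `[0, 1]`; the lower
#'   bound is exactly 0 when `k = 0` and the upper exactly 1 when `k = n`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  z <- stats::qnorm((1 + conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  low <- if (k == 0) 0 else max(0, center - half)
  high <- if (k == n) 1 else min(1, center + half)
  c(low = low, high = high)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Statistic `sum (O - E)^2 / E` without continuity correction (set
#' `yates = TRUE` for the corrected variant); p-value from chi-square with
#' 1 df. A zero row or column marginal yields `chi2 = 0`, `p = 1` with a
#' `degenerate` flag.
#'
#' @param a,b,c,d cell counts, rows = groups, columns = outcomes
#'   (`a b / c d`).
#' @param yates apply the continuity correction (default FALSE).
#' @return Named vector `c(chi2, p)` with attribute `"degenerate"`.
#' @export
chisq_2x2 <- function(a, b, c, d, yates = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) == 0) stop("counts must be >= 0 with positive total")
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  degenerate <- any(rs == 0) || any(cs == 0)
  if (degenerate) {
    out <- c(chi2 = 0, p = 1)
  } else {
    e <- outer(rs, cs) / n
    dev <- abs(tab - e)
    if (yates) dev <- pmax(dev - 0.5, 0)
    chi2 <- sum(dev^2 / e)
    out <- c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Annual anemia incidence with Wilson intervals and cohort comparison
#'
#' Consumes visit-level records (one row per individual per enrollment
#' year), flags anemia from HB and sex, and per (year, cohort) reports the
#' incidence rate with its Wilson 95% CI. When exactly two cohorts are
#' present, a per-year Pearson chi-square comparing them is attached.
#'
#' @param records `data.frame` with columns `individual_id`, `year`,
#'   `cohort`, `sex`, `HB`. An individual appearing twice within one year
#'   is an error.
#' @param conf confidence level for the Wilson intervals.
#' @return A `data.frame` with `year`, `cohort`, `n_tested`, `n_anemia`,
#'   `rate`, `ci_low`, `ci_high`, `chi2`, `p` (chi2/p repeated across the
#'   year's rows; `NA` unless exactly two cohorts).
#' @export
annual_incidence <- function(records, conf = 0.95) {
  need <- c("individual_id", "year", "cohort", "sex", "HB")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  dup <- duplicated(records[, c("individual_id", "year")])
  if (any(dup)) stop("duplicate individual within a year")
  records$anemia <- anemia_flag(records$HB, records$sex)

  out <- list()
  for (yr in sort(unique(records$year))) {
    sub <- records[records$year == yr, ]
    cohorts <- sort(unique(sub$cohort))
    rows <- lapply(cohorts, function(ch) {
      s <- sub[sub$cohort == ch, ]
      n <- nrow(s); k <- sum(s$anemia)
      ci <- wilson_ci(k, n, conf)
      data.frame(year = yr, cohort = ch, n_tested = n, n_anemia = k,
                 rate = k / n, ci_low = ci[["low"]], ci_high = ci[["high"]],
                 stringsAsFactors = FALSE)
    })
    yr_df <- do.call(rbind, rows)
    if (length(cohorts) == 2) {
      cs <- chisq_2x2(yr_df$n_anemia[1], yr_df$n_tested[1] - yr_df$n_anemia[1],
                      yr_df$n_anemia[2], yr_df$n_tested[2] - yr_df$n_anemia[2])
      yr_df$chi2 <- cs[["chi2"]]; yr_df$p <- cs[["p"]]
    } else {
      yr_df$chi2 <- NA_real_; yr_df$p <- NA_real_
    }
    out[[length(out) + 1L]] <- yr_df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multivariate HB-inflammation association across three model families
#'
#' Outcome: hemoglobin; predictors: the standardized inflammatory markers
#' plus the adjustment covariates (age, sex, disease duration, treatment;
#' categoricals one-hot with the reference level dropped). Three models are
#' fit: ordinary least squares (coefficients + Wald p, Bonferroni-corrected
#' over the markers only), ridge regression (penalty chosen by 5-fold CV
#' over a fixed log-spaced grid), and a random forest (permutation-free
#' impurity importance, normalized to sum to 1 over all predictors).
#'
#' @param clinical a clinical `data.frame` as from [generate_clinical()].
#' @param markers marker columns to test (default CRP, ESR, IL6, DAS28).
#' @param seed integer RNG seed (CV folds, forest).
#' @return A list with `markers` (data.frame: `marker`, `beta_lm`, `se_lm`,
#'   `p_lm`, `p_bonferroni`, `beta_ridge`, `rf_importance`, `significant`),
#'   `rf_importance_all` (named, sums to 1), `ridge_lambda`,
#'   `lm_condition_number`.
#' @export
hb_association <- function(clinical, markers = c("CRP", "ESR", "IL6", "DAS28"),
                           seed = 1) {
  need <- c("HB", "age", "sex", "disease_duration", "treatment", markers)
  missing <- setdiff(need, names(clinical))
  if (length(missing) > 0) stop("clinical table lacks: ", paste(missing, collapse = ", "))
  if (anyNA(clinical[, need])) stop("adjustment covariates and markers must be complete")

  df <- clinical
  for (mk in markers) df[[mk]] <- as.numeric(scale(df[[mk]]))
  fml <- stats::as.formula(paste(
    "HB ~", paste(c(markers, "age", "sex", "disease_duration", "treatment"),
                  collapse = " + ")
  ))

  lm_fit <- stats::lm(fml, data = df)
  sm <- summary(lm_fit)$coefficients
  beta_lm <- sm[markers, "Estimate"]
  se_lm <- sm[markers, "Std. Error"]
  p_lm <- sm[markers, "Pr(>|t|)"]
  p_bonf <- pmin(p_lm * length(markers), 1)

  mm <- stats::model.matrix(fml, df)[, -1, drop = FALSE]
  cond <- kappa(mm, exact = TRUE)

  withr::with_seed(check_seed(seed), {
    lambda_grid <- 10^seq(-4, 2, length.out = 60)
    cvr <- glmnet::cv.glmnet(mm, df$HB, alpha = 0, lambda = lambda_grid,
                             nfolds = 5, standardize = FALSE)
    beta_ridge_all <- as.numeric(stats::coef(cvr, s = "lambda.min"))[-1]
    names(beta_ridge_all) <- colnames(mm)

    rf <- randomForest::randomForest(mm, df$HB, ntree = 500, importance = FALSE)
    imp <- randomForest::importance(rf)[, 1]
    imp_norm <- imp / sum(imp)
  })

  list(
    markers = data.frame(
      marker = markers,
      beta_lm = unname(beta_lm), se_lm = unname(se_lm),
      p_lm = unname(p_lm), p_bonferroni = unname(p_bonf),
      beta_ridge = unname(beta_ridge_all[markers]),
      rf_importance = unname(imp_norm[markers]),
      significant = unname(p_bonf < 0.05),
      stringsAsFactors = FALSE
    ),
    rf_importance_all = imp_norm,
    ridge_lambda = cvr$lambda.min,
    lm_condition_number = cond
  )
}

#' Post hoc power of a two-sided two-sample t-test
#'
#' Exact noncentral-t evaluation: with `ncp = |d| * sqrt(n1 n2 / (n1 + n2))`
#' and `df = n1 + n2 - 2`,
#' `power = P(T > t_crit) + P(T < -t_crit)` under the noncentral
#' distribution. `d = 0` returns `alpha` exactly.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param d standardized effect size (Cohen's d; absolute value used).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
two_sample_power <- function(n1, n2, d, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("n1 and n2 must be >= 2")
  d <- abs(d)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp, lower.tail = TRUE)
}
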