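test_that("parameter validation rejects inconsistent settings", {
  expect_error(synth_omics_params(n_planted = 50, n_features = 20), "n_planted")
  expect_error(synth_omics_params(missing_rate = 0.6), "missing_rate")
  expect_error(synth_omics_params(n_per_group = 2.5), "integers")
  expect_error(synth_omics_params(dispersion_scale = -1), "dispersion_scale")
})

test_that("generators are pure functions of their parameters (seed included)", {
  p <- synth_omics_params(n_per_group = 10, n_features = 40, n_planted = 5,
                          seed = 7)
  a <- generate_transcriptome(p); b <- generate_transcriptome(p)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$planted_feature_ids, b$truth$planted_feature_ids)
  a2 <- generate_metabolome(p); b2 <- generate_metabolome(p)
  expect_identical(a2$matrix$values, b2$matrix$values)
  c1 <- generate_clinical(50, seed = 3); c2 <- generate_clinical(50, seed = 3)
  expect_identical(c1, c2)

  p2 <- synth_omics_params(n_per_group = 10, n_features = 40, n_planted = 5,
                           seed = 8)
  expect_false(identical(generate_transcriptome(p2)$matrix$values,
                         a$matrix$values))
})

test_that("transcriptome ground truth marks planted genes and zero effects", {
  p <- synth_omics_params(n_per_group = 15, n_features = 100, n_planted = 10,
                          effect_log2fc = 2, seed = 2)
  g <- generate_transcriptome(p)
  expect_length(g$truth$planted_feature_ids, 10)
  expect_true(all(g$truth$planted_feature_ids %in% feature_ids(g$matrix)))
  eff <- g$truth$effect
  expect_true(all(eff[g$truth$planted_feature_ids] == 2))
  expect_true(all(eff[setdiff(names(eff), g$truth$planted_feature_ids)] == 0))
  expect_true(all(g$matrix$values >= 0))
  # some genes exceed 50% zeros so the filter stage is exercised
  expect_gt(sum(colMeans(g$matrix$values == 0) > 0.5), 0)
})

test_that("metabolome masking exercises the missingness filter", {
  p <- synth_omics_params(n_per_group = 20, n_features = 100, n_planted = 5,
                          missing_rate = 0.05, high_missing_frac = 0.1, seed = 4)
  g <- generate_metabolome(p)
  frac <- colMeans(is.na(g$matrix$values))
  expect_gte(sum(frac > 0.2), 10) # the forced high-missing features
  expect_true(all(g$matrix$values > 0, na.rm = TRUE))
  # planted features are never forced above the filter threshold
  expect_true(all(frac[g$truth$planted_feature_ids] <= 0.25))

  p0 <- synth_omics_params(n_per_group = 20, n_features = 50, n_planted = 5,
                           missing_rate = 0, high_missing_frac = 0, seed = 4)
  g0 <- generate_metabolome(p0)
  expect_identical(
    ncol(filter_metabolite_missingness(g0$matrix)$values), 50L)
})

test_that("null metabolome gives uniform t-test p-values (~5% below 0.05)", {
  rates <- vapply(1:5, function(s) {
    p <- synth_omics_params(n_per_group = 20, n_features = 400, n_planted = 0,
                            missing_rate = 0, high_missing_frac = 0, seed = s)
    g <- generate_metabolome(p)
    m <- sum_normalize_log10(g$matrix)
    tt <- student_ttest(m, g$truth$group_assignment)
    mean(tt$p_value < 0.05)
  }, numeric(1))
  # 3 binomial SDs around 0.05 for 2000 pooled null features
  tol <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(rates) - 0.05), tol)
})

test_that("planted-feature recovery is monotone in effect size", {
  recovery <- vapply(c(0.5, 1.0, 1.5, 2.0), function(es) {
    p <- synth_omics_params(n_per_group = 30, n_features = 150, n_planted = 15,
                            effect_shift_sd = es, missing_rate = 0,
                            high_missing_frac = 0, seed = 11)
    g <- generate_metabolome(p)
    m <- sum_normalize_log10(g$matrix)
    tt <- student_ttest(m, g$truth$group_assignment)
    vip <- plsda_vip(m, g$truth$group_assignment)
    sel <- select_differential_metabolites(
      data.frame(tt, vip = vip[tt$feature_id]))
    length(intersect(sel, g$truth$planted_feature_ids)) / 15
  }, numeric(1))
  expect_true(all(diff(recovery) >= -1e-9))
  expect_gte(recovery[4], recovery[1])
})

test_that("clinical generator plants the HB-inflammation structure", {
  # noiseless-ish limit with only the ESR term: near-perfect correlation
  cl <- generate_clinical(400, seed = 5, beta_esr = -1, beta_crp = 0,
                          noise_sd = 1e-6)
  res <- stats::residuals(stats::lm(
    HB ~ age + sex + disease_duration + treatment, data = cl))
  resE <- stats::residuals(stats::lm(
    scale(ESR) ~ age + sex + disease_duration + treatment, data = cl))
  expect_lt(cor(res, resE), -0.999)
})

test_that("incidence generator respects planted rates and structure", {
  yrs <- 2020:2022
  rec <- generate_incidence(
    yrs,
    rates_by_cohort = list(RA = c(0, 0.5, 0.3), non_RA = c(0.1, 0.1, 0.1)),
    n_by_cohort = list(RA = c(50, 200, 100), non_RA = c(100, 100, 100)),
    seed = 9
  )
  inc <- annual_incidence(rec)
  r0 <- inc[inc$year == 2020 & inc$cohort == "RA", ]
  expect_equal(r0$n_anemia, 0) # rate 0 -> no cases
  expect_equal(r0$rate, 0)
  expect_error(
    generate_incidence(yrs, list(RA = c(0.1, 0.2)), list(RA = c(10, 10, 10))),
    "match the number of years")
  rec2 <- generate_incidence(yrs, list(RA = rep(0.4, 3)), list(RA = rep(30, 3)),
                             seed = 9)
  expect_identical(rec2, generate_incidence(yrs, list(RA = rep(0.4, 3)),
                                            list(RA = rep(30, 3)), seed = 9))
})
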