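test_that("anemia thresholds are sex-specific and strict", {
  expect_true(anemia_flag(119, "male"))
  expect_false(anemia_flag(120, "male"))
  expect_false(anemia_flag(110, "female"))
  expect_true(anemia_flag(109.9, "female"))
  expect_false(anemia_flag(115, "female"))
  expect_true(anemia_flag(115, "male"))
  expect_error(anemia_flag(100, "unknown"), "unknown sex")
  expect_error(anemia_flag(-5, "male"), "positive")
})

test_that("Wilson interval matches its closed form and the prop.test oracle", {
  ci <- wilson_ci(5, 10)
  expect_equal(unname(round(ci, 3)), c(0.237, 0.763))
  oracle <- prop.test(5, 10, correct = FALSE)$conf.int
  expect_equal(unname(ci), as.numeric(oracle), tolerance = 1e-10)
  expect_equal(wilson_ci(0, 20)[["low"]], 0)
  expect_equal(wilson_ci(20, 20)[["high"]], 1)
  for (k in c(1, 7, 19)) {
    o <- prop.test(k, 25, correct = FALSE)$conf.int
    expect_equal(unname(wilson_ci(k, 25)), as.numeric(o), tolerance = 1e-10)
  }
  expect_error(wilson_ci(5, 0), "n must be")
  expect_error(wilson_ci(11, 10), "k must lie")
})

test_that("Wilson interval coverage sits in the nominal band", {
  withr::with_seed(71, {
    covered <- vapply(1:1000, function(i) {
      k <- rbinom(1, 50, 0.3)
      ci <- wilson_ci(k, 50)
      ci[["low"]] <= 0.3 && 0.3 <= ci[["high"]]
    }, logical(1))
  })
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("chi-square matches brute force and the stats::chisq.test oracle", {
  brute <- function(a, b, c, d) {
    tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  out <- chisq_2x2(30, 70, 10, 90)
  expect_equal(out[["chi2"]], 12.5)
  expect_equal(out[["p"]], 4.07e-4, tolerance = 1e-2)
  expect_equal(as.numeric(chisq_2x2(10, 10, 10, 10)), c(0, 1))
  # row swap symmetry
  expect_equal(chisq_2x2(10, 90, 30, 70)[["chi2"]], out[["chi2"]])
  withr::with_seed(72, {
    for (i in 1:100) {
      cts <- rpois(4, 20) + 1
      mine <- chisq_2x2(cts[1], cts[2], cts[3], cts[4])
      expect_lt(abs(mine[["chi2"]] - brute(cts[1], cts[2], cts[3], cts[4])),
                1e-10)
      oracle <- suppressWarnings(
        chisq.test(matrix(cts, 2, 2, byrow = TRUE), correct = FALSE))
      expect_equal(mine[["p"]], oracle$p.value, tolerance = 1e-12)
    }
  })
  degen <- chisq_2x2(0, 0, 5, 5)
  expect_equal(as.numeric(degen), c(0, 1))
  expect_true(attr(degen, "degenerate"))
})

test_that("annual incidence assembles counts, CIs and cohort comparisons", {
  rec <- generate_incidence(
    2020:2021,
    rates_by_cohort = list(RA = c(0.4, 0.4), non_RA = c(0.1, 0.1)),
    n_by_cohort = list(RA = c(2000, 2000), non_RA = c(2000, 2000)),
    seed = 12
  )
  inc <- annual_incidence(rec)
  expect_identical(nrow(inc), 4L)
  expect_true(all(inc$ci_low <= inc$rate & inc$rate <= inc$ci_high))
  expect_true(all(inc$n_anemia <= inc$n_tested))
  # planted 0.4 vs 0.1 at n = 2000 is overwhelmingly significant
  expect_true(all(inc$p < 0.001))
  ra <- inc[inc$cohort == "RA", ]
  expect_lt(max(abs(ra$rate - 0.4)), 0.05)
  # duplicated individual within a year is rejected
  rec2 <- rbind(rec, rec[1, ])
  expect_error(annual_incidence(rec2), "duplicate individual")
})

test_that("HB association recovers a planted coefficient across models", {
  cl <- generate_clinical(1000, seed = 81, beta_esr = -0.4, beta_crp = -0.25)
  res <- hb_association(cl, seed = 2)
  esr <- res$markers[res$markers$marker == "ESR", ]
  expect_lt(abs(esr$beta_lm - (-0.4)), 0.08)
  expect_true(esr$significant)
  # linear and ridge agree in sign; forest importance normalized
  expect_identical(sign(esr$beta_lm), sign(esr$beta_ridge))
  expect_equal(sum(res$rf_importance_all), 1, tolerance = 1e-12)
  expect_identical(hb_association(cl, seed = 2)$markers, res$markers)
})

test_that("null markers stay non-significant after Bonferroni", {
  hits <- vapply(1:30, function(s) {
    cl <- generate_clinical(200, seed = 500 + s, beta_esr = 0, beta_crp = 0)
    res <- hb_association(cl, seed = s)
    any(res$markers$significant)
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("t-test power matches the stats::power.t.test oracle", {
  expect_equal(two_sample_power(64, 64, 0.5), 0.8015, tolerance = 1e-3)
  for (n in c(10, 30, 100)) {
    oracle <- power.t.test(n = n, delta = 0.7, sd = 1)$power
    # power.t.test ignores the opposite-tail rejection region; the
    # exact two-tailed evaluation differs from it below 1e-3
    expect_equal(two_sample_power(n, n, 0.7), oracle, tolerance = 1e-3)
  }
  expect_equal(two_sample_power(20, 20, 0), 0.05)
  # monotone in n, symmetric in the sign of d
  p1 <- two_sample_power(20, 20, 0.5)
  p2 <- two_sample_power(40, 40, 0.5)
  expect_gt(p2, p1)
  expect_equal(two_sample_power(20, 20, -0.5), p1)
  expect_error(two_sample_power(1, 20, 0.5), "must be >= 2")
})
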