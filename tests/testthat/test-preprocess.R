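test_that("missingness filter removes strictly above 20% and keeps order", {
  x <- matrix(rlnorm(10 * 3), 10, 3,
              dimnames = list(sprintf("S%02d", 1:10), c("a", "b", "c")))
  x[1:3, 1] <- NA # 30% missing -> removed
  x[1:2, 2] <- NA # exactly 20% -> retained (strict >)
  m <- omics_matrix(x, "metabolome")
  f <- filter_metabolite_missingness(m)
  expect_identical(feature_ids(f), c("b", "c"))
  expect_identical(attr(f, "removed"), "a")

  # fully observed matrix unchanged
  m2 <- omics_matrix(matrix(rlnorm(20), 5, 4), "metabolome")
  expect_identical(filter_metabolite_missingness(m2)$values, m2$values)

  # everything above threshold -> error
  x3 <- matrix(rlnorm(12), 4, 3)
  x3[1:2, ] <- NA
  expect_error(filter_metabolite_missingness(omics_matrix(x3, "metabolome")),
               "nothing left")
})

test_that("min imputation fills with the per-feature observed minimum", {
  x <- matrix(c(NA, 2, 4,
                5, NA, NA,
                1, 1, 1), 3, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  m <- impute_min(omics_matrix(x, "metabolome"))
  expect_equal(m$values[, "f1"], c(2, 2, 4), ignore_attr = TRUE)
  expect_equal(m$values[, "f2"], c(5, 5, 5), ignore_attr = TRUE)
  expect_equal(m$values[, "f3"], c(1, 1, 1), ignore_attr = TRUE)

  # no missing values -> identity
  m2 <- omics_matrix(matrix(rlnorm(12), 4, 3), "metabolome")
  expect_identical(impute_min(m2)$values, m2$values)

  # all-missing feature -> error
  x3 <- matrix(c(NA, NA, 1, 2), 2, 2)
  expect_error(impute_min(omics_matrix(x3, "metabolome")), "zero observed")
})

test_that("sum normalization conserves row totals and is scale invariant", {
  x <- rbind(c(1, 1, 1, 1), c(2, 2, 2, 2), c(9999, 1, 1e-9, 1e-9))
  x <- x[, 1:4]
  m <- omics_matrix(matrix(c(1, 1, 1, 1, 2, 2, 2, 2), 2, 4, byrow = TRUE),
                    "metabolome")
  out <- sum_normalize_log10(m)
  # equal values per sample, and rows that are scalar multiples coincide
  expect_equal(unname(out$values[1, ]), rep(log10(2500), 4))
  expect_equal(out$values[1, ], out$values[2, ], ignore_attr = TRUE)
  # back-transformed rows sum to the constant
  expect_equal(unname(rowSums(10^out$values)), c(1e4, 1e4))

  # hand computation for an extreme sample
  m2 <- omics_matrix(matrix(c(9999, 1), 1, 2), "metabolome")
  out2 <- sum_normalize_log10(m2)
  expect_equal(unname(out2$values[1, ]),
               c(log10(9999 / 10000 * 1e4), log10(1 / 10000 * 1e4)))

  expect_error(sum_normalize_log10(omics_matrix(matrix(c(0, 1), 1, 2),
                                                "metabolome")),
               "strictly positive")
})

test_that("zero-row filter removes strictly above 50% zeros", {
  x <- matrix(5L, 10, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  x[1:6, 1] <- 0L # 60% zeros -> removed
  x[1:5, 2] <- 0L # exactly 50% -> retained
  m <- omics_matrix(x + 0, "transcriptome")
  f <- filter_zero_rows(m)
  expect_identical(feature_ids(f), c("g2", "g3"))

  # all-zero gene removed; dense matrix unchanged
  x2 <- cbind(g1 = rep(0, 6), g2 = rep(3, 6))
  f2 <- filter_zero_rows(omics_matrix(x2, "transcriptome"))
  expect_identical(feature_ids(f2), "g2")
})

test_that("filters are idempotent and ordering is stable", {
  p <- synth_omics_params(n_per_group = 10, n_features = 60, n_planted = 5,
                          missing_rate = 0.1, high_missing_frac = 0.1, seed = 6)
  g <- generate_metabolome(p)
  f1 <- filter_metabolite_missingness(g$matrix)
  f2 <- filter_metabolite_missingness(f1)
  expect_identical(f1$values, f2$values)
  expect_identical(feature_ids(f1),
                   intersect(feature_ids(g$matrix), feature_ids(f1)))

  gt <- generate_transcriptome(p)
  z1 <- filter_zero_rows(gt$matrix)
  z2 <- filter_zero_rows(z1)
  expect_identical(z1$values, z2$values)
})

test_that("median-of-ratios size factors match hand-computed toys", {
  # all samples identical -> all factors 1
  x <- matrix(rep(c(10L, 20L, 30L, 40L, 50L), each = 4), 4, 5)
  m <- omics_matrix(x + 0, "transcriptome")
  expect_equal(unname(size_factors_median_of_ratios(m)), rep(1, 4))

  # doubling one sample doubles its factor relative to the others
  x2 <- x; x2[2, ] <- x2[2, ] * 2L
  sf <- size_factors_median_of_ratios(omics_matrix(x2 + 0, "transcriptome"))
  expect_equal(unname(sf[2] / sf[1]), 2)

  # single sample -> factor 1
  m1 <- omics_matrix(matrix(c(3, 8, 2), 1, 3), "transcriptome")
  expect_equal(unname(size_factors_median_of_ratios(m1)), 1)

  # no gene expressed everywhere -> error
  x3 <- rbind(c(0, 5), c(5, 0))
  expect_error(size_factors_median_of_ratios(omics_matrix(x3, "transcriptome")),
               "no gene")
})
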