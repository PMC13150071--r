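test_that("VIP satisfies its normalization identity on arbitrary inputs", {
  for (s in 1:5) {
    m <- make_shifted_matrix(10, 15 + s, n_signal = 3, shift = 1, seed = s)
    vip <- plsda_vip(m, m$groups)
    expect_lt(abs(mean(vip^2) - 1), 1e-8)
  }
})

test_that("identical informative copies all get VIP exactly 1", {
  withr::with_seed(2, {
    base <- rnorm(20) + rep(c(0, 2), each = 10)
    x <- matrix(rep(base, 6), 20, 6,
                dimnames = list(NULL, sprintf("f%d", 1:6)))
    x <- x + 0 # identical columns
    m <- omics_matrix(x, "metabolome",
                      rep(c("RA", "RA_ane"), each = 10))
    vip <- plsda_vip(m, m$groups, n_components = 1)
    expect_equal(unname(vip), rep(1, 6), tolerance = 1e-10)
  })
})

test_that("planted informative features exceed VIP 1 among noise", {
  m <- make_shifted_matrix(15, 20, n_signal = 2, shift = 2, seed = 42)
  vip <- plsda_vip(m, m$groups)
  expect_true(all(vip[c("f001", "f002")] > 1))
})

test_that("plain one-component VIP agrees with the mixOmics oracle", {
  skip_if_not_installed("mixOmics")
  m <- make_shifted_matrix(12, 8, n_signal = 2, shift = 1.5, seed = 5)
  mine <- plsda_vip(m, m$groups, n_components = 1)
  fit <- mixOmics::plsda(scale(m$values), m$groups, ncomp = 1)
  oracle <- mixOmics::vip(fit)[, 1]
  expect_equal(unname(mine[names(oracle)]), unname(oracle), tolerance = 1e-6)
})

test_that("t-test matches stats::t.test and flags degenerate features", {
  withr::with_seed(7, {
    x <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, paste0("f", 1:4)))
    x[, 4] <- 1 # zero pooled variance
    g <- rep(c("RA", "RA_ane"), each = 6)
    res <- student_ttest(omics_matrix(x, "metabolome"), g)
    for (j in 1:3) {
      or <- t.test(x[7:12, j], x[1:6, j], var.equal = TRUE)
      expect_equal(res$statistic[j], unname(or$statistic), tolerance = 1e-12)
      expect_equal(res$p_value[j], or$p.value, tolerance = 1e-12)
    }
    expect_true(res$degenerate[4])
    expect_equal(res$p_value[4], 1)
    expect_equal(res$statistic[4], 0)
  })
})

test_that("metabolite selection rule applies strict thresholds", {
  tab <- data.frame(
    feature_id = paste0("f", 1:5),
    vip = c(1.2, 0.8, 1.5, 1.1, 1.0),
    p_value = c(0.01, 0.01, 0.2, 0.04, 0.001)
  )
  expect_identical(select_differential_metabolites(tab), c("f1", "f4"))
  # vip exactly 1.0 excluded even with tiny p (f5); empty result allowed
  tab2 <- data.frame(feature_id = "x", vip = 0.5, p_value = 0.5)
  expect_length(select_differential_metabolites(tab2), 0)
  tab$vip[1] <- NA
  expect_error(select_differential_metabolites(tab), "present for all")
})

test_that("BH adjustment reproduces the hand-derived step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, NA)), "not allowed")
  expect_error(bh_fdr(c(0.1, 1.2)), "lie in")
})

test_that("NB Wald flags planted genes and respects label symmetry", {
  p <- synth_omics_params(n_per_group = 20, n_features = 150, n_planted = 10,
                          effect_log2fc = 2, zero_gene_frac = 0.05, seed = 21)
  g <- generate_transcriptome(p)
  filt <- filter_zero_rows(g$matrix)
  sf <- size_factors_median_of_ratios(filt)
  de <- nb_wald_de(filt, g$truth$group_assignment, sf)
  planted <- intersect(g$truth$planted_feature_ids, de$feature_id)
  recall <- mean(de$significant[match(planted, de$feature_id)])
  expect_gte(recall, 0.8)
  # false positives rare at FDR < 0.01
  nulls <- setdiff(de$feature_id, planted)
  expect_lte(sum(de$significant[match(nulls, de$feature_id)]), 2)

  # swapping labels negates log2_fc, p unchanged
  y <- g$truth$group_assignment
  y_sw <- factor(ifelse(y == "RA", "RA_ane", "RA"), levels = c("RA", "RA_ane"))
  de_sw <- nb_wald_de(filt, y_sw, sf)
  expect_equal(de_sw$log2_fc, -de$log2_fc, tolerance = 1e-8)
  expect_equal(de_sw$p_value, de$p_value, tolerance = 1e-8)
})

test_that("NB Wald direction agrees with the DESeq2 oracle on a fixture", {
  skip_if_not_installed("DESeq2")
  p <- synth_omics_params(n_per_group = 12, n_features = 80, n_planted = 8,
                          effect_log2fc = 2, zero_gene_frac = 0, seed = 31)
  g <- generate_transcriptome(p)
  filt <- filter_zero_rows(g$matrix)
  de <- nb_wald_de(filt, g$truth$group_assignment)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = t(filt$values),
      colData = data.frame(group = g$truth$group_assignment),
      design = ~group
    )
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  ref <- res[de$feature_id, ]
  # direction agreement on clearly moved genes, rank agreement overall
  strong <- which(abs(ref$log2FoldChange) > 1)
  expect_gte(mean(sign(de$log2_fc[strong]) ==
                    sign(ref$log2FoldChange[strong])), 0.95)
  expect_gte(cor(de$log2_fc, ref$log2FoldChange, use = "complete.obs"), 0.9)
})

test_that("fold-change filter is inclusive at the threshold", {
  withr::with_seed(9, {
    n <- 40
    g <- rep(c("RA", "RA_ane"), each = n / 2)
    # integer group means 5 and 6 give fold change 6/5 = 1.2 exactly
    x <- cbind(
      hit = ifelse(g == "RA_ane", 0, -1) + rep(c(5, 7), n / 2),
      null = rep(c(4, 6), n / 2),
      noisy = rlnorm(n, meanlog = 3, sdlog = 1)
    )
    res <- fold_change_filter(omics_matrix(x, "proteome"), g)
    hit <- res[res$feature_id == "hit", ]
    expect_identical(hit$fold_change, 1.2)
    expect_true(hit$significant) # inclusive >=
    expect_false(res$significant[res$feature_id == "null"])
    expect_error(fold_change_filter(omics_matrix(-x, "proteome"), g),
                 "strictly positive")
  })
})
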