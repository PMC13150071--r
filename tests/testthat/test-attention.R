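test_that("modality defaults encode the two analysis configurations", {
  met <- attention_config("metabolome")
  txn <- attention_config("transcriptome")
  expect_identical(met$n_components, 10L)
  expect_identical(txn$n_components, 30L)
  expect_identical(met$n_heads, 2L)
  expect_identical(txn$n_heads, 6L)
  expect_equal(met$learning_rate, 5e-4)
  expect_equal(txn$learning_rate, 1e-4)
  expect_identical(met$patience, 8L)
  expect_identical(txn$patience, 10L)
  for (cfg in list(met, txn)) {
    expect_identical(cfg$n_layers, 3L)
    expect_equal(cfg$dropout, 0.5)
    expect_equal(cfg$weight_decay, 0.1)
    expect_identical(cfg$n_folds, 5L)
  }
  expect_error(attention_config("metabolome", embed_dim = 25), "divisible")
  expect_error(attention_config("metabolome", nonsense = 1), "unknown config")
})

test_that("fold_fit_transform confines the fit to the training rows", {
  withr::with_seed(11, {
    tr <- matrix(rnorm(30 * 12), 30, 12,
                 dimnames = list(NULL, sprintf("f%02d", 1:12)))
    te <- matrix(rnorm(10 * 12), 10, 12,
                 dimnames = list(NULL, colnames(tr)))
  })
  ft <- fold_fit_transform(tr, te, 5)
  # orthonormal loadings, non-increasing explained variance
  expect_equal(crossprod(ft$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(ft$explained_variance) <= 1e-10))
  # test = train gives identical scores
  ft2 <- fold_fit_transform(tr, tr, 5)
  expect_equal(ft2$train_scores, ft2$test_scores)
  # full-rank round trip reconstructs the standardized matrix
  ftf <- fold_fit_transform(tr, te, 12)
  xs <- apply_scaler_for_test(tr, ftf$scaler)
  expect_equal(ftf$train_scores %*% t(ftf$loadings), xs, tolerance = 1e-6)
  expect_error(fold_fit_transform(tr, te, 13), "n_components exceeds")
})

test_that("attention rows are simplexes and importances sum to one", {
  withr::with_seed(12, {
    S <- matrix(rnorm(40 * 6), 40, 6)
    y <- rep(0:1, 20)
  })
  cfg <- tiny_attention_config(n_components = 6, seed = 3)
  model <- train_encoder(S, y, cfg)
  loadings <- matrix(rnorm(50 * 6), 50, 6,
                     dimnames = list(sprintf("f%02d", 1:50), NULL))
  ai <- attention_importance(model, S, loadings)
  expect_lt(ai$attention_row_max_dev, 1e-6)
  expect_equal(sum(ai$component_importance), 1, tolerance = 1e-10)
  expect_true(all(ai$component_importance >= 0))
  expect_length(ai$feature_importance, 50)
})

test_that("importance mapping is loading-weighted and sign-invariant", {
  loadings <- rbind(
    dominant = c(0.95, 0.05),
    minor1 = c(0.2, 0.6),
    minor2 = c(0.1, 0.7)
  )
  comp_imp <- c(0.9, 0.1) # PC1 dominates attention
  fi <- map_component_importance(loadings, comp_imp)
  expect_identical(names(which.max(fi)), "dominant")
  # sign flips of components change nothing
  fi_flip <- map_component_importance(loadings %*% diag(c(-1, 1)), comp_imp)
  expect_equal(unname(fi_flip), unname(fi))
})

test_that("top-fraction selection sizes and tie handling are exact", {
  imp <- stats::setNames(c(5, 4, 3, 2, 1), paste0("f", 1:5))
  expect_identical(select_top_fraction(imp, 0.4), c("f1", "f2"))
  imp100 <- stats::setNames(runif(100), sprintf("f%03d", 1:100))
  expect_length(select_top_fraction(imp100, 0.2), 20)
  ties <- stats::setNames(rep(1, 10), sprintf("f%02d", 10:1))
  expect_identical(select_top_fraction(ties, 0.2),
                   c("f01", "f02")) # lexicographic tie-break
})

test_that("dual filter is a guarded set intersection", {
  expect_identical(dual_filter(c("a", "b", "c"), c("b", "c", "d")), c("b", "c"))
  expect_identical(dual_filter(c("a", "b"), c("a", "b")), c("a", "b"))
  expect_message(out <- dual_filter("a", "b"), "empty intersection")
  expect_length(out, 0)
  expect_error(dual_filter(c("a", "z"), "a", universe = c("a", "b")),
               "universe")
})

test_that("confined cross-validation separates signal from permuted labels", {
  m <- make_shifted_matrix(40, 12, n_signal = 2, shift = 3, seed = 21)
  # a learning rate high enough to converge inside the patience window at
  # this toy scale
  cfg <- tiny_attention_config(n_components = 5, seed = 13, n_folds = 5,
                               max_epochs = 120, learning_rate = 5e-3)
  rep_sig <- cross_validate(m, m$groups, cfg)
  expect_gte(rep_sig$mean_auc, 0.85)
  # stratification contract
  tab <- table(rep_sig$fold_assignment, m$groups)
  expect_lte(diff(range(rowSums(tab))), 1)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))
  # determinism
  rep_sig2 <- cross_validate(m, m$groups, cfg)
  expect_identical(rep_sig$importance, rep_sig2$importance)
  expect_identical(rep_sig$fold_metrics, rep_sig2$fold_metrics)
  # selected set size
  expect_length(rep_sig$selected, ceiling(0.2 * 12))

  withr::with_seed(99, yp <- sample(as.integer(m$groups) - 1L))
  rep_null <- cross_validate(m, yp, cfg)
  expect_gte(rep_null$mean_auc, 0.3)
  expect_lte(rep_null$mean_auc, 0.7)
})
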