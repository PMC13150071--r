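#' ROC AUC via the Mann-Whitney identity
#'
#' Probability that a random positive outscores a random negative, with ties
#' counted 1/2; equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric score vector (larger = more positive).
#' @param labels binary labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores) # midranks handle ties as 1/2 wins
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, precision, recall and F1 of the positive class. Zero-denominator
#' cases (no predicted positives, no true positives) return 0 and are
#' flagged via the `"degenerate"` attribute.
#'
#' @param pred_labels predicted binary labels.
#' @param true_labels true binary labels.
#' @return Named numeric vector `(accuracy, precision, recall, f1)`.
#' @export
classification_metrics <- function(pred_labels, true_labels) {
  yp <- as_binary01(pred_labels)
  yt <- as_binary01(true_labels)
  if (length(yp) != length(yt)) stop("length mismatch")
  tp <- sum(yp == 1 & yt == 1); fp <- sum(yp == 1 & yt == 0)
  fn <- sum(yp == 0 & yt == 1); tn <- sum(yp == 0 & yt == 0)
  acc <- (tp + tn) / length(yt)
  degenerate <- character(0)
  if (tp + fp == 0) degenerate <- c(degenerate, "precision")
  if (tp + fn == 0) degenerate <- c(degenerate, "recall")
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  out <- c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
  attr(out, "degenerate") <- degenerate
  out
}

#' Average precision (area under the precision-recall step curve)
#'
#' `AP = sum_k (R_k - R_{k-1}) * P_k` over descending score thresholds
#' (tied scores form a single threshold).
#'
#' @inheritParams roc_auc
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  y <- as_binary01(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys)
  n_pred <- seq_along(ys)
  # thresholds at the last index of each tied block
  thr <- which(!duplicated(ss, fromLast = TRUE))
  prec <- tp[thr] / n_pred[thr]
  rec <- tp[thr] / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Quantile-bin calibration table
#'
#' Splits samples into `n_bins` equal-count bins of predicted probability
#' (quantile breaks; tied probabilities stay together, so fewer effective
#' bins can result) and reports mean predicted probability versus observed
#' positive frequency per bin.
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param labels binary labels.
#' @param n_bins number of quantile bins (default 5).
#' @return A `data.frame` with `bin`, `mean_predicted`, `observed_freq`, `n`.
#' @export
calibration_bins <- function(probs, labels, n_bins = 5) {
  y <- as_binary01(labels)
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  if (length(probs) < n_bins) stop("need at least n_bins samples")
  breaks <- unique(stats::quantile(probs, seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(breaks) == 1) {
    rep(1L, length(probs)) # constant probabilities: one effective bin
  } else {
    as.integer(cut(probs, breaks, include.lowest = TRUE))
  }
  agg <- lapply(sort(unique(bin)), function(b) {
    idx <- bin == b
    data.frame(bin = b, mean_predicted = mean(probs[idx]),
               observed_freq = mean(y[idx]), n = sum(idx))
  })
  do.call(rbind, agg)
}

#' Bootstrap percentile CI for an AUC difference
#'
#' Resamples each dataset independently, stratified by class (so every
#' resample retains both classes), and returns the percentile confidence
#' interval of `AUC_a - AUC_b`.
#'
#' @param scores_a,labels_a first score/label set.
#' @param scores_b,labels_b second score/label set.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed integer RNG seed.
#' @return Numeric vector `c(lower, upper)` with attribute `"estimate"`
#'   (the observed difference).
#' @export
bootstrap_auc_diff_ci <- function(scores_a, labels_a, scores_b, labels_b,
                                  n_boot = 2000, conf = 0.95, seed = 1) {
  ya <- as_binary01(labels_a); yb <- as_binary01(labels_b)
  obs <- roc_auc(scores_a, ya) - roc_auc(scores_b, yb)
  strat_resample <- function(y) {
    pos <- which(y == 1); neg <- which(y == 0)
    c(sample(pos, length(pos), replace = TRUE),
      sample(neg, length(neg), replace = TRUE))
  }
  withr::with_seed(check_seed(seed), {
    diffs <- vapply(seq_len(n_boot), function(i) {
      ia <- strat_resample(ya); ib <- strat_resample(yb)
      roc_auc(scores_a[ia], ya[ia]) - roc_auc(scores_b[ib], yb[ib])
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- stats::quantile(diffs, c(alpha, 1 - alpha), names = FALSE)
    structure(c(lower = ci[1], upper = ci[2]), estimate = obs)
  })
}

#' Spearman correlation of omics features with clinical variables
#'
#' For every (feature, clinical variable) pair over the shared samples:
#' Spearman rho, two-sided p, and BH-FDR across the whole matrix.
#'
#' @param m an `omics_matrix` (no missing values).
#' @param clinical a clinical `data.frame` with a `sample_id` column.
#' @param variables clinical columns to correlate (default HB, CRP, ESR,
#'   IL6, DAS28).
#' @return A list of feature x variable matrices: `rho`, `p`, `fdr`.
#' @export
feature_clinical_correlation <- function(m, clinical,
                                         variables = c("HB", "CRP", "ESR", "IL6", "DAS28")) {
  stopifnot(inherits(m, "omics_matrix"))
  shared <- intersect(sample_ids(m), clinical$sample_id)
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  x <- m$values[shared, , drop = FALSE]
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  missing_vars <- setdiff(variables, names(cl))
  if (length(missing_vars) > 0) stop("clinical table lacks: ", paste(missing_vars, collapse = ", "))

  rho <- p <- matrix(NA_real_, ncol(x), length(variables),
                     dimnames = list(colnames(x), variables))
  for (v in variables) {
    for (j in seq_len(ncol(x))) {
      ct <- suppressWarnings(
        stats::cor.test(x[, j], cl[[v]], method = "spearman", exact = FALSE)
      )
      rho[j, v] <- unname(ct$estimate)
      p[j, v] <- ct$p.value
    }
  }
  fdr <- matrix(bh_fdr(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  list(rho = rho, p = p, fdr = fdr)
}
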