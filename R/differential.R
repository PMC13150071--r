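#' PLS-DA variable importance in projection (with orthogonal signal removal)
#'
#' Computes per-feature VIP scores from a NIPALS partial-least-squares
#' discriminant model. Following the orthogonal-projection construction,
#' `n_components - 1` Y-orthogonal components are first estimated and removed
#' from the (column-standardized) predictor matrix, then a single predictive
#' component is fit and VIP is computed from it:
#' `VIP_j = sqrt(p * sum_a w_ja^2 * SSY_a / sum_a SSY_a)`, which guarantees
#' `mean(VIP^2) = 1`.
#'
#' @param m an `omics_matrix` (features are column-standardized internally;
#'   constant features are dropped with a warning and receive VIP `NA`).
#' @param labels binary class labels aligned to samples.
#' @param n_components total components: 1 predictive plus
#'   `n_components - 1` orthogonal (default 2, i.e. one orthogonal).
#' @return Named numeric vector of VIP scores (one per feature).
#' @export
plsda_vip <- function(m, labels, n_components = 2) {
  stopifnot(inherits(m, "omics_matrix"), n_components >= 1)
  y01 <- as_binary01(labels)
  if (length(unique(y01)) < 2) stop("labels contain a single class")
  if (min(table(y01)) < 3) stop("need at least 3 samples per group")
  x <- m$values
  if (anyNA(x)) stop("missing values present; preprocess first")

  sds <- apply(x, 2, stats::sd)
  const <- sds < .Machine$double.eps
  if (any(const)) {
    warning(sum(const), " constant feature(s) dropped from VIP computation")
  }
  keep <- which(!const)
  xs <- scale(x[, keep, drop = FALSE])
  y <- as.numeric(scale(y01))

  # remove (n_components - 1) Y-orthogonal components
  for (a in seq_len(n_components - 1)) {
    w <- drop(crossprod(xs, y))
    w <- w / sqrt(sum(w^2))
    t_pred <- drop(xs %*% w)
    p_load <- drop(crossprod(xs, t_pred)) / sum(t_pred^2)
    w_orth <- p_load - drop(crossprod(w, p_load)) * w
    nw <- sqrt(sum(w_orth^2))
    if (nw < 1e-12) break # nothing orthogonal left to remove
    w_orth <- w_orth / nw
    t_orth <- drop(xs %*% w_orth)
    p_orth <- drop(crossprod(xs, t_orth)) / sum(t_orth^2)
    xs <- xs - tcrossprod(t_orth, p_orth)
  }

  # one predictive NIPALS component
  w <- drop(crossprod(xs, y))
  w <- w / sqrt(sum(w^2))

  p <- length(keep)
  vip <- sqrt(p * w^2) # single component: SSY weights cancel
  out <- rep(NA_real_, ncol(x))
  out[keep] <- vip
  stats::setNames(out, colnames(x))
}

#' Per-feature two-sided Student's t-test (pooled variance)
#'
#' @param m an `omics_matrix` on the analysis (e.g. log10) scale.
#' @param labels binary class labels.
#' @return A `data.frame` with `feature_id`, `statistic`, `p_value`,
#'   `degenerate` (TRUE where the pooled variance is zero; such features get
#'   `statistic = 0`, `p_value = 1`).
#' @export
student_ttest <- function(m, labels) {
  stopifnot(inherits(m, "omics_matrix"))
  y <- as_binary01(labels)
  if (min(table(y)) < 2) stop("need at least 2 samples per group")
  x <- m$values
  if (anyNA(x)) stop("missing values present; preprocess first")
  g1 <- x[y == 0, , drop = FALSE]
  g2 <- x[y == 1, , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2)
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- apply(g1, 2, stats::var); v2 <- apply(g2, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  degenerate <- se < .Machine$double.eps
  tstat <- ifelse(degenerate, 0, (m2 - m1) / se)
  pval <- ifelse(degenerate, 1,
                 2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE))
  data.frame(feature_id = colnames(x), statistic = tstat, p_value = pval,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select differential metabolites by the VIP / P rule
#'
#' Keeps features with `vip > vip_min` and `p < p_max`, both strict, the
#' composite threshold used for metabolite screening.
#'
#' @param res a `data.frame` with columns `feature_id`, `vip`, `p_value`.
#' @param vip_min VIP threshold (strict `>`), default 1.0.
#' @param p_max P threshold (strict `<`), default 0.05.
#' @return Character vector of selected feature ids (possibly empty).
#' @export
select_differential_metabolites <- function(res, vip_min = 1.0, p_max = 0.05) {
  stopifnot(all(c("feature_id", "vip", "p_value") %in% names(res)))
  if (anyNA(res$vip) || anyNA(res$p_value)) {
    stop("vip and p_value must be present for all features")
  }
  res$feature_id[res$vip > vip_min & res$p_value < p_max]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone in p-rank, capped at 1).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) stop("NaN/NA p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Per-group NB mean MLE with log link and offsets: solves
# sum_i (k_i - sf_i * m) / (1 + phi * sf_i * m) = 0 for beta = log(m),
# identical to the group coefficient of a two-group NB GLM (orthogonal
# design). Returns beta, Fisher information, and a convergence flag.
nb_group_fit <- function(k, sf, phi, max_iter = 50L, tol = 1e-10) {
  if (sum(k) == 0) { # degenerate: no counts in this group
    m0 <- 0.5 / sum(sf)
    return(list(beta = log(m0), info = sum(sf * m0), converged = FALSE))
  }
  beta <- log(sum(k) / sum(sf))
  for (it in seq_len(max_iter)) {
    mu <- sf * exp(beta)
    w <- 1 + phi * mu
    score <- sum((k - mu) / w)
    info <- sum(mu * (1 + phi * k) / w^2) # -E[d2l] approx via observed info
    if (!is.finite(info) || info <= 0) break
    step <- score / info
    beta <- beta + step
    if (abs(step) < tol) {
      mu <- sf * exp(beta)
      return(list(beta = beta,
                  info = sum(mu / (1 + phi * mu)), # expected information
                  converged = TRUE))
    }
  }
  mu <- sf * exp(beta)
  list(beta = beta, info = sum(mu / (1 + phi * mu)), converged = FALSE)
}

#' Negative-binomial Wald differential expression
#'
#' Two-group differential expression on filtered counts: per-gene
#' method-of-moments dispersion estimated from normalized counts (floored at
#' `1e-8`), per-group negative-binomial mean fits with log link and
#' size-factor offsets (equivalent to a two-group NB GLM), a standard-normal
#' Wald test on the group log-fold-change, and Benjamini-Hochberg
#' correction.
#' Genes whose fit does not converge fall back to a quasi-Poisson
#' approximation and are flagged.
#'
#' Fold change is computed from the mean normalized counts of each group
#' (group 2 over group 1, with a 0.5 pseudo-mean only when a group mean is
#' zero); `|FC|` is the symmetric `max(FC, 1/FC)`.
#'
#' @param counts a transcriptome `omics_matrix`, already zero-row filtered.
#' @param labels binary class labels (second level = group 2).
#' @param size_factors positive per-sample size factors
#'   (default: [size_factors_median_of_ratios()]).
#' @param fdr_max FDR threshold for the significance flag (strict `<`).
#' @param fc_min fold-change threshold for the significance flag
#'   (strict `>`, symmetric).
#' @return A `data.frame` with columns `feature_id`, `mean_g1`, `mean_g2`,
#'   `fold_change`, `log2_fc`, `statistic`, `p_value`, `fdr`, `significant`,
#'   `direction`, `converged`.
#' @export
nb_wald_de <- function(counts, labels, size_factors = NULL,
                       fdr_max = 0.01, fc_min = 2.0) {
  stopifnot(inherits(counts, "omics_matrix"), counts$modality == "transcriptome")
  y <- as_binary01(labels)
  x <- counts$values
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(counts)
  if (any(size_factors <= 0)) stop("size factors must be positive")
  norm <- sweep(x, 1, size_factors, "/")

  g1 <- y == 0; g2 <- y == 1
  n <- nrow(x)
  res <- vapply(seq_len(ncol(x)), function(j) {
    k <- x[, j]
    q <- norm[, j]
    mu_hat <- mean(q)
    # method-of-moments dispersion on normalized counts (pooled within-group)
    v_within <- (sum((q[g1] - mean(q[g1]))^2) + sum((q[g2] - mean(q[g2]))^2)) / (n - 2)
    phi <- max((v_within - mu_hat) / mu_hat^2, 1e-8)
    f1 <- nb_group_fit(k[g1], size_factors[g1], phi)
    f2 <- nb_group_fit(k[g2], size_factors[g2], phi)
    converged <- f1$converged && f2$converged
    if (!converged) {
      # quasi-Poisson fallback: beta = log(sum k / sum sf), dispersion from
      # Pearson residuals
      b1 <- log(max(sum(k[g1]), 0.5) / sum(size_factors[g1]))
      b2 <- log(max(sum(k[g2]), 0.5) / sum(size_factors[g2]))
      mu <- size_factors * exp(ifelse(g2, b2, b1))
      disp <- max(sum((k - mu)^2 / mu) / (n - 2), 1)
      se <- sqrt(disp * (1 / sum(mu[g1]) + 1 / sum(mu[g2])))
      wald <- (b2 - b1) / se
    } else {
      wald <- (f2$beta - f1$beta) / sqrt(1 / f1$info + 1 / f2$info)
    }
    c(wald = wald, converged = as.numeric(converged))
  }, numeric(2))

  wald <- res["wald", ]
  pval <- 2 * stats::pnorm(abs(wald), lower.tail = FALSE)
  fdr <- bh_fdr(pval)

  m1 <- colMeans(norm[g1, , drop = FALSE])
  m2 <- colMeans(norm[g2, , drop = FALSE])
  zero <- m1 == 0 | m2 == 0
  fc <- ifelse(zero, (m2 + 0.5) / (m1 + 0.5), m2 / m1)
  abs_fc <- pmax(fc, 1 / fc)

  data.frame(
    feature_id = colnames(x),
    mean_g1 = m1, mean_g2 = m2,
    fold_change = fc, log2_fc = log2(fc),
    statistic = wald, p_value = pval, fdr = fdr,
    significant = fdr < fdr_max & abs_fc > fc_min,
    direction = ifelse(fc >= 1, "up", "down"),
    converged = res["converged", ] == 1,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fold-change plus t-test filter (proteomics-style)
#'
#' Significance rule on positive linear-scale values: symmetric
#' `|FC| = max(FC, 1/FC) >= fc_min` (inclusive) and pooled-variance t-test
#' `p < p_max` on log-transformed values.
#'
#' @param m an `omics_matrix` with strictly positive linear-scale values.
#' @param labels binary class labels.
#' @param fc_min fold-change threshold (inclusive `>=`), default 1.2.
#' @param p_max P threshold (strict `<`), default 0.05.
#' @return A `data.frame` with `feature_id`, `mean_g1`, `mean_g2`,
#'   `fold_change`, `log2_fc`, `statistic`, `p_value`, `significant`.
#' @export
fold_change_filter <- function(m, labels, fc_min = 1.2, p_max = 0.05) {
  stopifnot(inherits(m, "omics_matrix"))
  if (anyNA(m$values)) stop("missing values present; preprocess first")
  if (any(m$values <= 0)) stop("values must be strictly positive on the linear scale")
  y <- as_binary01(labels)
  logm <- omics_matrix(log10(m$values), m$modality, m$groups)
  tt <- student_ttest(logm, labels)
  m1 <- colMeans(m$values[y == 0, , drop = FALSE])
  m2 <- colMeans(m$values[y == 1, , drop = FALSE])
  fc <- m2 / m1
  abs_fc <- pmax(fc, 1 / fc)
  data.frame(
    feature_id = tt$feature_id,
    mean_g1 = m1, mean_g2 = m2,
    fold_change = fc, log2_fc = log2(fc),
    statistic = tt$statistic, p_value = tt$p_value,
    significant = abs_fc >= fc_min & tt$p_value < p_max,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
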