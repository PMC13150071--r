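#' Stratified train/test split
#'
#' Disjoint, exhaustive, class-stratified split: within each class
#' `round(train_frac * n_class)` samples go to training, so the class ratio
#' is preserved within one sample.
#'
#' @param sample_ids character vector.
#' @param labels binary labels aligned to `sample_ids`.
#' @param train_frac training fraction (default 0.7).
#' @param seed integer RNG seed.
#' @return A list with `train` and `test` id vectors.
#' @export
stratified_split <- function(sample_ids, labels, train_frac = 0.7, seed = 1) {
  y <- as_binary01(labels)
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  withr::with_seed(check_seed(seed), {
    train <- character(0)
    for (cls in c(0L, 1L)) {
      ids <- sample_ids[y == cls]
      n_tr <- round(train_frac * length(ids))
      n_tr <- min(max(n_tr, 1), length(ids) - 1) # keep both partitions non-empty
      train <- c(train, sample(ids, n_tr))
    }
    list(train = sample_ids[sample_ids %in% train],
         test = sample_ids[!sample_ids %in% train])
  })
}

#' Fit a small-panel diagnostic classifier
#'
#' L2-regularized (ridge) logistic regression on the panel features.
#' Standardization is fit on the training partition only, mirroring the
#' leakage confinement used elsewhere in the package; the L2 penalty keeps
#' coefficients finite under perfect separation.
#'
#' @param m an `omics_matrix` containing (at least) the panel features.
#' @param labels binary labels aligned to samples of `m`.
#' @param panel character vector of panel feature ids (typically 5).
#' @param split a list with `train`/`test` sample ids
#'   (default: [stratified_split()] at 7:3 using `seed`).
#' @param lambda ridge penalty (default 0.05).
#' @param seed integer RNG seed (used for the default split).
#' @return An object of class `panel_model`: `panel`, `coefficients`
#'   (including intercept), `scaler`, `split`, `lambda`.
#' @export
fit_panel <- function(m, labels, panel, split = NULL, lambda = 0.05, seed = 1) {
  stopifnot(inherits(m, "omics_matrix"))
  missing <- setdiff(panel, feature_ids(m))
  if (length(missing) > 0) stop("panel features absent from matrix: ",
                                paste(missing, collapse = ", "))
  y <- as_binary01(labels)
  names(y) <- sample_ids(m)
  if (is.null(split)) {
    split <- stratified_split(sample_ids(m), labels, train_frac = 0.7, seed = seed)
  }
  if (length(intersect(split$train, split$test)) > 0) stop("train/test overlap")

  xtr <- m$values[split$train, panel, drop = FALSE]
  scaler <- fit_scaler(xtr)
  xtr_s <- apply_scaler(xtr, scaler)
  fit <- glmnet::glmnet(xtr_s, y[split$train], family = "binomial",
                        alpha = 0, lambda = lambda, standardize = FALSE)
  coefs <- as.numeric(stats::coef(fit, s = lambda))
  names(coefs) <- c("(Intercept)", panel)

  structure(
    list(panel = panel, coefficients = coefs, scaler = scaler,
         split = split, lambda = lambda),
    class = "panel_model"
  )
}

#' Predict panel-model probabilities
#' @param model a `panel_model`.
#' @param m an `omics_matrix` containing the panel features.
#' @param samples sample ids to predict (default all).
#' @return Named vector of positive-class probabilities.
#' @export
predict_panel <- function(model, m, samples = sample_ids(m)) {
  unseen <- setdiff(model$panel, feature_ids(m))
  if (length(unseen) > 0) stop("matrix lacks panel features: ",
                               paste(unseen, collapse = ", "))
  x <- apply_scaler(m$values[samples, model$panel, drop = FALSE], model$scaler)
  eta <- drop(x %*% model$coefficients[-1]) + model$coefficients[1]
  stats::setNames(stats::plogis(eta), samples)
}

#' Evaluate a fitted panel model on its train and test partitions
#'
#' Full metric array on both partitions: AUC, accuracy/precision/recall/F1
#' at a 0.5 threshold, average precision, and a 5-quantile-bin calibration
#' table.
#'
#' @param model a `panel_model`.
#' @param m the `omics_matrix` the model was fit on (or a compatible one).
#' @param labels binary labels aligned to samples of `m`.
#' @param n_bins calibration bins (default 5).
#' @return A list with `train` and `test`, each containing `metrics` (named
#'   vector with `auc`, `accuracy`, `precision`, `recall`, `f1`, `ap`) and
#'   `calibration` (data.frame).
#' @export
evaluate_panel <- function(model, m, labels, n_bins = 5) {
  stopifnot(inherits(model, "panel_model"))
  y <- as_binary01(labels)
  names(y) <- sample_ids(m)
  eval_part <- function(ids) {
    p <- predict_panel(model, m, ids)
    yt <- y[ids]
    cm <- classification_metrics(as.integer(p >= 0.5), yt)
    list(
      metrics = c(auc = roc_auc(p, yt), cm, ap = average_precision(p, yt)),
      calibration = calibration_bins(p, yt,
                                     n_bins = min(n_bins, length(ids)))
    )
  }
  list(train = eval_part(model$split$train),
       test = eval_part(model$split$test))
}
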