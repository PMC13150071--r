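#' Configuration for the PCA-transformer attention pipeline
#'
#' Modality-specific defaults: metabolome uses 10 principal components, 2
#' attention heads, learning rate 5e-4 and early-stopping patience 8;
#' transcriptome uses 30 components, 6 heads, learning rate 1e-4 and
#' patience 10. Both use a 3-layer encoder, dropout 0.5, L2 weight decay
#' 0.1 and 5-fold stratified cross-validation.
#'
#' @param modality `"metabolome"` or `"transcriptome"`.
#' @param ... overrides for any config field (`n_components`, `n_layers`,
#'   `n_heads`, `embed_dim`, `ff_dim`, `dropout`, `weight_decay`,
#'   `learning_rate`, `patience`, `max_epochs`, `batch_size`,
#'   `top_fraction`, `n_folds`, `seed`).
#' @return A list of class `attention_config`.
#' @export
attention_config <- function(modality = c("metabolome", "transcriptome"), ...) {
  modality <- match.arg(modality)
  cfg <- list(
    modality = modality,
    n_components = if (modality == "metabolome") 10L else 30L,
    n_layers = 3L,
    n_heads = if (modality == "metabolome") 2L else 6L,
    embed_dim = 24L,
    ff_dim = 48L,
    dropout = 0.5,
    weight_decay = 0.1,
    learning_rate = if (modality == "metabolome") 5e-4 else 1e-4,
    patience = if (modality == "metabolome") 8L else 10L,
    max_epochs = 200L,
    batch_size = 4L,
    top_fraction = 0.20,
    n_folds = 5L,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$embed_dim %% cfg$n_heads != 0) stop("embed_dim must be divisible by n_heads")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must lie in [0, 1)")
  if (cfg$n_folds < 2) stop("n_folds must be >= 2")
  if (cfg$top_fraction <= 0 || cfg$top_fraction >= 1) stop("top_fraction must lie in (0, 1)")
  cfg$seed <- check_seed(cfg$seed)
  structure(cfg, class = "attention_config")
}

#' @rdname attention_config
#' @export
default_config <- attention_config

#' Leakage-confined scaler + PCA for one cross-validation fold
#'
#' Standardization and PCA are fit exclusively on the training rows and then
#' applied to both partitions. Loadings are orthonormal and component
#' variances are non-increasing.
#'
#' @param train,test numeric matrices (samples x features) with identical
#'   feature columns.
#' @param n_components number of PCs (`<= min(n_train - 1, n_features)`).
#' @return A list with `train_scores`, `test_scores`, `loadings`
#'   (features x components), `scaler` (train means/SDs), and
#'   `explained_variance`.
#' @export
fold_fit_transform <- function(train, test, n_components) {
  if (n_components > min(nrow(train) - 1, ncol(train))) {
    stop("n_components exceeds min(n_train - 1, n_features)")
  }
  scaler <- fit_scaler(train)
  tr <- apply_scaler(train, scaler)
  te <- apply_scaler(test, scaler)
  sv <- svd(tr, nu = 0, nv = n_components)
  loadings <- sv$v
  rownames(loadings) <- colnames(train)
  ev <- sv$d[seq_len(n_components)]^2 / (nrow(train) - 1)
  list(train_scores = tr %*% loadings,
       test_scores = te %*% loadings,
       loadings = loadings,
       scaler = scaler,
       explained_variance = ev)
}

# attention the classification token pays to each component token, averaged
# over samples within each (layer, head), then combined across heads and
# layers with negentropy weights: a head whose attention is uniform over
# components is uninformative about feature relevance and receives ~zero
# weight, while a selective head dominates. Renormalized to sum to 1 over
# components; with every head uniform the result degrades gracefully to the
# uniform distribution.
component_attention <- function(model, scores, chunk = 32L) {
  if (!is.null(model$input_scaler)) {
    scores <- apply_scaler(scores, model$input_scaler)
  }
  C <- ncol(scores)
  n <- nrow(scores)
  n_mats <- model$config$n_layers * model$config$n_heads
  acc_mat <- matrix(0, n_mats, C) # per (layer, head) sample-summed attention
  max_row_dev <- 0
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    B <- length(idx)
    C_tok <- C + 1L # classification token occupies position 1
    cls_rows <- seq(1L, B * C_tok, by = C_tok)
    fwd <- encoder_forward(model$params, scores[idx, , drop = FALSE],
                           model$config, collect_attention = TRUE)
    r <- 0L
    for (layer in fwd$attn) { # (B*C_tok) x C_tok x H stacked softmax rows
      for (h in seq_len(dim(layer)[3])) {
        P <- layer[, , h]
        max_row_dev <- max(max_row_dev, max(abs(rowSums(P) - 1)))
        r <- r + 1L
        acc_mat[r, ] <- acc_mat[r, ] + colSums(P[cls_rows, -1, drop = FALSE])
      }
    }
  }
  dist <- acc_mat / rowSums(acc_mat) # mean attention distribution per matrix
  negent <- apply(dist, 1, function(a) {
    a <- a[a > 0]
    log(C) + sum(a * log(a)) # 0 for uniform, log(C) for one-hot
  })
  acc <- drop(crossprod(dist, negent + 1e-12))
  list(importance = acc / sum(acc), max_row_dev = max_row_dev)
}

#' Map component importance to original features
#'
#' Per-feature importance is the absolute-loading-weighted sum of component
#' importances, `imp_f = sum_c |loading_fc| * imp_c`; it is invariant to PCA
#' sign flips.
#'
#' @param loadings features x components loading matrix (rownames = ids).
#' @param component_importance non-negative vector summing to 1.
#' @return Named numeric vector of per-feature importances.
#' @export
map_component_importance <- function(loadings, component_importance) {
  stopifnot(ncol(loadings) == length(component_importance))
  drop(abs(loadings) %*% component_importance)
}

#' Attention-derived importance for one trained fold
#'
#' Per-component importance is the attention the classification token pays
#' to each component token, averaged over heads, layers and samples and
#' renormalized to sum to 1 over components; per-feature importance
#' propagates it through absolute PCA loadings.
#'
#' @param model a trained `attn_encoder`.
#' @param scores PC score matrix to evaluate attention on.
#' @param loadings the fold's PCA loading matrix.
#' @return A list with `component_importance`, `feature_importance`, and
#'   `attention_row_max_dev` (largest deviation of any softmax row sum
#'   from 1).
#' @export
attention_importance <- function(model, scores, loadings) {
  stopifnot(inherits(model, "attn_encoder"))
  ca <- component_attention(model, scores)
  list(component_importance = ca$importance,
       feature_importance = map_component_importance(loadings, ca$importance),
       attention_row_max_dev = ca$max_row_dev)
}

#' Select the top fraction of features by importance
#'
#' Returns the `ceiling(top_fraction * p)` highest-importance features.
#' Boundary ties are broken lexicographically by feature id, so the
#' selection is reproducible.
#'
#' @param importance named numeric vector (names = feature ids).
#' @param top_fraction fraction to keep, in (0, 1).
#' @return Character vector of selected feature ids.
#' @export
select_top_fraction <- function(importance, top_fraction = 0.20) {
  if (!all(is.finite(importance))) stop("importances must be finite")
  if (is.null(names(importance))) stop("importance vector must be named")
  k <- ceiling(top_fraction * length(importance))
  ord <- order(-importance, names(importance))
  names(importance)[ord[seq_len(k)]]
}

#' Intersect classical differential features with attention-selected ones
#'
#' The dual filter: features that are both classically differential and in
#' the attention top fraction. An empty intersection is permitted (a message
#' is emitted).
#'
#' @param differential_set,attention_set character vectors of feature ids.
#' @param universe optional character vector; when supplied, both sets must
#'   be subsets of it (an error is raised otherwise).
#' @return Character vector of intersecting feature ids.
#' @export
dual_filter <- function(differential_set, attention_set, universe = NULL) {
  if (!is.null(universe)) {
    out1 <- setdiff(differential_set, universe)
    out2 <- setdiff(attention_set, universe)
    if (length(out1) > 0 || length(out2) > 0) {
      stop("sets are not over the same feature universe")
    }
  }
  res <- intersect(differential_set, attention_set)
  if (length(res) == 0) message("dual filter: empty intersection")
  res
}

#' Confined stratified cross-validation of the PCA-transformer
#'
#' Runs `n_folds` stratified cross-validation. Within each fold the scaler,
#' PCA and encoder are fit on the training portion only and evaluated on the
#' held-out fold (AUC, accuracy, precision, recall, F1 at a 0.5 threshold).
#' Per-feature attention importance is computed per fold (on the fold's
#' training scores) and averaged across folds.
#'
#' The deliberate-leakage mode (`leakage = "full"`) exists only as a
#' regression probe of the confinement: it fits the scaler and PCA on all
#' samples and uses the held-out fold as the early-stopping validation set,
#' so label information leaks into model selection and the permuted-label
#' AUC inflates above 0.5.
#'
#' @param m an `omics_matrix` with no missing values (preprocessed scale).
#' @param labels binary labels aligned to samples.
#' @param config an [attention_config()].
#' @param leakage `"none"` (confined, default) or `"full"`.
#' @return An object of class `attention_report`: `fold_metrics`
#'   (data.frame), `importance` (named vector, fold-averaged),
#'   `component_importance` (folds x components matrix), `selected`
#'   (top-fraction feature set), `histories`, `fold_assignment`,
#'   `mean_auc`.
#' @export
cross_validate <- function(m, labels, config, leakage = c("none", "full")) {
  stopifnot(inherits(m, "omics_matrix"))
  leakage <- match.arg(leakage)
  y <- as_binary01(labels)
  if (min(table(y)) < config$n_folds) stop("need at least n_folds samples per class")
  x <- m$values
  if (anyNA(x)) stop("missing values present; preprocess first")

  withr::with_seed(config$seed, {
    fold <- stratified_folds(y, config$n_folds)
    imp_sum <- stats::setNames(numeric(ncol(x)), colnames(x))
    comp_imp <- matrix(NA_real_, config$n_folds, config$n_components)
    metrics <- vector("list", config$n_folds)
    histories <- vector("list", config$n_folds)

    leak_fit <- if (leakage == "full") {
      fold_fit_transform(x, x, config$n_components)
    }

    for (f in seq_len(config$n_folds)) {
      tr <- fold != f
      if (leakage == "full") {
        tr_scores <- leak_fit$train_scores[tr, , drop = FALSE]
        te_scores <- leak_fit$train_scores[!tr, , drop = FALSE]
        loadings <- leak_fit$loadings
        val_data <- list(scores = te_scores, labels = y[!tr])
      } else {
        ft <- fold_fit_transform(x[tr, , drop = FALSE], x[!tr, , drop = FALSE],
                                 config$n_components)
        tr_scores <- ft$train_scores
        te_scores <- ft$test_scores
        loadings <- ft$loadings
        val_data <- NULL
      }
      cfg_f <- config
      cfg_f$seed <- child_seed(config$seed, f)
      model <- train_encoder(tr_scores, y[tr], cfg_f, val_data = val_data)
      histories[[f]] <- model$history

      p_te <- predict_encoder(model, te_scores)
      y_te <- y[!tr]
      cm <- classification_metrics(as.integer(p_te >= 0.5), y_te)
      metrics[[f]] <- data.frame(
        fold = f,
        auc = roc_auc(p_te, y_te),
        accuracy = cm["accuracy"], precision = cm["precision"],
        recall = cm["recall"], f1 = cm["f1"],
        stopped_epoch = model$stopped_epoch, row.names = NULL
      )

      ai <- attention_importance(model, tr_scores, loadings)
      comp_imp[f, ] <- ai$component_importance
      imp_sum <- imp_sum + ai$feature_importance
    }

    fold_metrics <- do.call(rbind, metrics)
    importance <- imp_sum / config$n_folds
    structure(
      list(fold_metrics = fold_metrics,
           importance = importance,
           component_importance = comp_imp,
           selected = select_top_fraction(importance, config$top_fraction),
           histories = histories,
           fold_assignment = fold,
           mean_auc = mean(fold_metrics$auc),
           leakage = leakage),
      class = "attention_report"
    )
  })
}

#' @export
print.attention_report <- function(x, ...) {
  cat(sprintf(
    "<attention_report> %d-fold CV, mean AUC %.3f; %d features selected (top fraction)\n",
    nrow(x$fold_metrics), x$mean_auc, length(x$selected)
  ))
  invisible(x)
}
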