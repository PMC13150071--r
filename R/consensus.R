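# Five-model algorithmic consensus: per-model top-k rankings and their
# intersection. Models: KNN (k = 5), RBF SVM, random forest (500 trees),
# recursive feature elimination RF, and gradient-boosted trees (xgboost,
# 200 rounds, depth 3). KNN and SVM have no native importance and use
# seeded permutation importance (20 repeats, AUC drop).

CONSENSUS_MODELS <- c("KNN", "SVM", "RF", "RFE-RF", "XGBoost")

# permutation importance: AUC drop when one column is permuted at
# prediction time, averaged over n_rep permutations
permutation_importance <- function(x, y, predict_fun, n_rep = 20) {
  base_auc <- roc_auc(predict_fun(x), y)
  imp <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    drops <- vapply(seq_len(n_rep), function(r) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(x)), j]
      base_auc - roc_auc(predict_fun(xp), y)
    }, numeric(1))
    imp[j] <- mean(drops)
  }
  stats::setNames(imp, colnames(x))
}

knn_prob <- function(train_x, train_y, test_x, k = 5) {
  pr <- class::knn(train_x, test_x, factor(train_y), k = k, prob = TRUE)
  win <- attr(pr, "prob")
  ifelse(pr == "1", win, 1 - win)
}

rf_fit <- function(x, y) {
  randomForest::randomForest(x, factor(y), ntree = 500)
}

xgb_fit <- function(x, y) {
  dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                  nthread = 1, seed = 1),
    dtrain, nrounds = 200, verbose = 0
  )
}

svm_fit <- function(x, y) {
  e1071::svm(x, factor(y), kernel = "radial", probability = TRUE)
}

svm_prob <- function(fit, x) {
  p <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
  p[, "1"]
}

# RFE with random forest: repeatedly drop the worst half of features by RF
# importance; rank = reverse elimination order (survivors ranked by final
# importance).
rfe_rf_ranking <- function(x, y) {
  remaining <- colnames(x)
  rank_order <- character(0)
  while (length(remaining) > 1) {
    fit <- rf_fit(x[, remaining, drop = FALSE], y)
    imp <- randomForest::importance(fit)[, 1]
    imp <- imp[order(-imp, names(imp))]
    n_drop <- max(1, floor(length(remaining) / 2))
    dropped <- names(utils::tail(imp, n_drop))
    rank_order <- c(dropped[order(imp[dropped], decreasing = FALSE)], rank_order)
    remaining <- setdiff(remaining, dropped)
  }
  c(remaining, rank_order) # best first
}

#' Rank candidate features with one consensus model
#'
#' Fits the named model on the standardized candidate matrix and returns the
#' top `k` features by that model's importance: impurity importance for RF,
#' gain for XGBoost, elimination order for RFE-RF, and seeded permutation
#' importance (20 repeats, AUC drop at prediction time) for KNN and SVM.
#' Ties are broken lexicographically by feature id.
#'
#' @param m an `omics_matrix` restricted to the candidate features.
#' @param labels binary labels.
#' @param model_name one of `"KNN"`, `"SVM"`, `"RF"`, `"RFE-RF"`,
#'   `"XGBoost"`.
#' @param k list length (default 10; if `k > n_features` all features are
#'   ranked).
#' @param seed integer RNG seed.
#' @return Character vector of feature ids, best first, length
#'   `min(k, n_features)`.
#' @export
rank_features <- function(m, labels, model_name, k = 10, seed = 1) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!model_name %in% CONSENSUS_MODELS) {
    stop("unknown model_name; use one of: ", paste(CONSENSUS_MODELS, collapse = ", "))
  }
  y <- as_binary01(labels)
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  x <- scale(m$values)
  x[, apply(m$values, 2, stats::sd) == 0] <- 0
  k <- min(k, ncol(x))

  withr::with_seed(check_seed(seed), {
    imp <- switch(model_name,
      "RF" = {
        fit <- rf_fit(x, y)
        randomForest::importance(fit)[, 1]
      },
      "XGBoost" = {
        fit <- xgb_fit(x, y)
        tab <- xgboost::xgb.importance(model = fit)
        full <- stats::setNames(numeric(ncol(x)), colnames(x))
        full[tab$Feature] <- tab$Gain
        full
      },
      "KNN" = permutation_importance(x, y, function(xp) knn_prob(x, y, xp)),
      "SVM" = {
        fit <- svm_fit(x, y)
        permutation_importance(x, y, function(xp) svm_prob(fit, xp))
      },
      "RFE-RF" = {
        ranking <- rfe_rf_ranking(x, y)
        stats::setNames(rev(seq_along(ranking))[match(colnames(x), ranking)],
                        colnames(x))
      }
    )
    ord <- order(-imp, names(imp))
    names(imp)[ord[seq_len(k)]]
  })
}

#' Consensus intersection of per-model rankings
#'
#' Features present in every top-k list, ordered by ascending mean rank.
#'
#' @param lists a list of 5 ranked feature-id vectors (best first).
#' @return Character vector of consensus feature ids.
#' @export
consensus_intersection <- function(lists) {
  if (length(lists) < 5) stop("consensus requires 5 ranked lists")
  common <- Reduce(intersect, lists)
  if (length(common) == 0) return(character(0))
  mean_rank <- vapply(common, function(f) {
    mean(vapply(lists, function(l) match(f, l), numeric(1)))
  }, numeric(1))
  common[order(mean_rank, common)]
}

#' Build a five-model consensus panel
#'
#' Runs [rank_features()] for all five models and intersects the top-k
#' lists.
#'
#' @inheritParams rank_features
#' @return A list of class `consensus_panel`: `rankings` (named list of
#'   per-model top-k vectors), `intersection`, `k`.
#' @export
consensus_panel <- function(m, labels, k = 10, seed = 1) {
  rankings <- lapply(stats::setNames(CONSENSUS_MODELS, CONSENSUS_MODELS),
                     function(mod) {
                       rank_features(m, labels, mod, k = k,
                                     seed = child_seed(seed, match(mod, CONSENSUS_MODELS)))
                     })
  structure(
    list(rankings = rankings,
         intersection = consensus_intersection(rankings),
         k = k),
    class = "consensus_panel"
  )
}

#' Benchmark the five consensus models by stratified cross-validation
#'
#' Per model and fold: fit on the training portion (standardization fit on
#' the training portion only), predict probabilities on the held-out fold,
#' and compute AUC, accuracy, precision, recall, F1 (0.5 threshold). For
#' RFE-RF the feature elimination runs inside each training fold, keeping
#' the top half, before the final RF fit.
#'
#' @param m an `omics_matrix`.
#' @param labels binary labels.
#' @param n_folds number of stratified folds (default 5).
#' @param seed integer RNG seed.
#' @return A list with `summary` (5 models x 5 metrics, "mean +/- sd"
#'   formatting in `pretty`), `mean` and `sd` numeric matrices, and
#'   `per_fold` (long data.frame).
#' @export
benchmark_models <- function(m, labels, n_folds = 5, seed = 1) {
  stopifnot(inherits(m, "omics_matrix"))
  y <- as_binary01(labels)
  metrics_names <- c("auc", "accuracy", "precision", "recall", "f1")

  withr::with_seed(check_seed(seed), {
    fold <- stratified_folds(y, n_folds)
    rows <- list()
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      scaler <- fit_scaler(m$values[tr, , drop = FALSE])
      xtr <- apply_scaler(m$values[tr, , drop = FALSE], scaler)
      xte <- apply_scaler(m$values[!tr, , drop = FALSE], scaler)
      ytr <- y[tr]; yte <- y[!tr]
      if (length(unique(yte)) < 2) stop("degenerate single-class fold")

      probs <- list(
        "KNN" = knn_prob(xtr, ytr, xte),
        "SVM" = { fit <- svm_fit(xtr, ytr); svm_prob(fit, xte) },
        "RF" = stats::predict(rf_fit(xtr, ytr), xte, type = "prob")[, "1"],
        "RFE-RF" = {
          keep <- utils::head(rfe_rf_ranking(xtr, ytr),
                              max(2, ceiling(ncol(xtr) / 2)))
          fit <- rf_fit(xtr[, keep, drop = FALSE], ytr)
          stats::predict(fit, xte[, keep, drop = FALSE], type = "prob")[, "1"]
        },
        "XGBoost" = {
          fit <- xgb_fit(xtr, ytr)
          stats::predict(fit, xte)
        }
      )
      for (mod in CONSENSUS_MODELS) {
        p <- probs[[mod]]
        cm <- classification_metrics(as.integer(p >= 0.5), yte)
        rows[[length(rows) + 1L]] <- data.frame(
          model = mod, fold = f, auc = roc_auc(p, yte),
          accuracy = cm["accuracy"], precision = cm["precision"],
          recall = cm["recall"], f1 = cm["f1"], row.names = NULL
        )
      }
    }
    per_fold <- do.call(rbind, rows)
    mean_mat <- sd_mat <- matrix(NA_real_, length(CONSENSUS_MODELS),
                                 length(metrics_names),
                                 dimnames = list(CONSENSUS_MODELS, metrics_names))
    for (mod in CONSENSUS_MODELS) {
      sub <- per_fold[per_fold$model == mod, metrics_names]
      mean_mat[mod, ] <- colMeans(sub)
      sd_mat[mod, ] <- apply(sub, 2, stats::sd)
    }
    pretty <- matrix(sprintf("%.3f +/- %.3f", mean_mat, sd_mat),
                     nrow(mean_mat), ncol(mean_mat),
                     dimnames = dimnames(mean_mat))
    list(summary = as.data.frame(pretty), mean = mean_mat, sd = sd_mat,
         per_fold = per_fold)
  })
}
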