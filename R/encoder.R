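# Multi-head self-attention transformer encoder over principal-component
# tokens, written in plain matrix algebra with hand-derived backpropagation.
# A sample's C-dimensional PC score vector becomes C + 1 tokens: a learned
# classification token (position 1, score fixed at 0) followed by one token
# per component, each scalar score linearly embedded to embed_dim via a
# shared learned weight/bias plus a learned positional embedding. The
# classifier head reads only the classification token, so label-relevant
# information must flow through the attention its token pays to the
# component tokens — which is what makes those attention weights an
# importance measure. Batches are processed as one (B*(C+1)) x d token
# matrix; attention is restricted to tokens of the same sample via
# block-structured kernels.

row_softmax <- function(x) {
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  e / rowSums(e)
}

# broadcast helpers: multiply/add a length-ncol vector across columns
# (element (i, j) sees v[j]); faster than sweep() in the training loop
scale_cols <- function(x, v) x * rep(v, each = nrow(x))
add_cols <- function(x, v) x + rep(v, each = nrow(x))

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = add_cols(scale_cols(xhat, g), b), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- scale_cols(dy, g)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dg = dg, db = db)
}

glorot <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

attn_init_params <- function(n_tokens, cfg) {
  d <- cfg$embed_dim
  dff <- cfg$ff_dim
  p <- list(
    w_embed = glorot(d, 1)[, 1],
    b_embed = numeric(d),
    pos = glorot(n_tokens, d),
    lnf_g = rep(1, d),
    lnf_b = numeric(d),
    w_out = glorot(d, 1)[, 1],
    b_out = 0
  )
  for (l in seq_len(cfg$n_layers)) {
    p[[sprintf("L%d_Wq", l)]] <- glorot(d, d)
    p[[sprintf("L%d_Wk", l)]] <- glorot(d, d)
    p[[sprintf("L%d_Wv", l)]] <- glorot(d, d)
    p[[sprintf("L%d_Wo", l)]] <- glorot(d, d)
    p[[sprintf("L%d_ln1_g", l)]] <- rep(1, d)
    p[[sprintf("L%d_ln1_b", l)]] <- numeric(d)
    p[[sprintf("L%d_W1", l)]] <- glorot(d, dff)
    p[[sprintf("L%d_b1", l)]] <- numeric(dff)
    p[[sprintf("L%d_W2", l)]] <- glorot(dff, d)
    p[[sprintf("L%d_b2", l)]] <- numeric(d)
    p[[sprintf("L%d_ln2_g", l)]] <- rep(1, d)
    p[[sprintf("L%d_ln2_b", l)]] <- numeric(d)
  }
  p
}

# Forward pass. S: B x C score matrix. Returns probabilities plus (optionally)
# the cache needed for backprop and/or the per-layer/per-head attention
# matrices. Dropout masks are drawn from the current RNG when training = TRUE.
encoder_forward <- function(params, S, cfg, training = FALSE,
                            keep_cache = FALSE, collect_attention = FALSE) {
  B <- nrow(S); C <- ncol(S) + 1L # +1: classification token first
  d <- cfg$embed_dim; H <- cfg$n_heads; dh <- d / H
  drop_p <- if (training) cfg$dropout else 0
  sample_idx <- rep(seq_len(B), each = C)
  comp_idx <- rep(seq_len(C), times = B)
  cls_rows <- seq(1L, B * C, by = C)

  s_vec <- as.vector(t(cbind(0, S))) # classification token carries score 0
  X <- add_cols(outer(s_vec, params$w_embed), params$b_embed) +
    params$pos[comp_idx, , drop = FALSE]

  cache <- if (keep_cache) list(s_vec = s_vec, comp_idx = comp_idx,
                                sample_idx = sample_idx, cls_rows = cls_rows,
                                layers = vector("list", cfg$n_layers))
  attn <- if (collect_attention) vector("list", cfg$n_layers)

  # pre-normalization encoder layers: X <- X + MHSA(LN(X)),
  # X <- X + FFN(LN(X)), with a final LN before the readout — trains stably
  # at small batch sizes without a warmup schedule
  for (l in seq_len(cfg$n_layers)) {
    Wq <- params[[sprintf("L%d_Wq", l)]]; Wk <- params[[sprintf("L%d_Wk", l)]]
    Wv <- params[[sprintf("L%d_Wv", l)]]; Wo <- params[[sprintf("L%d_Wo", l)]]
    ln1 <- layernorm_fwd(X, params[[sprintf("L%d_ln1_g", l)]],
                         params[[sprintf("L%d_ln1_b", l)]])
    N1 <- ln1$y
    Q <- N1 %*% Wq; K <- N1 %*% Wk; V <- N1 %*% Wv
    ba <- block_attn_fwd(Q, K, V, B, C, H)
    Oc <- ba$O
    P_heads <- ba$P # (B*C) x C x H stacked softmax rows
    O2 <- Oc %*% Wo
    mask1 <- NULL
    if (drop_p > 0) {
      mask1 <- matrix((stats::runif(length(O2)) >= drop_p) / (1 - drop_p),
                      nrow(O2), ncol(O2))
      O2 <- O2 * mask1
    }
    X1 <- X + O2
    ln2 <- layernorm_fwd(X1, params[[sprintf("L%d_ln2_g", l)]],
                         params[[sprintf("L%d_ln2_b", l)]])
    N2 <- ln2$y
    Hpre <- add_cols(N2 %*% params[[sprintf("L%d_W1", l)]],
                     params[[sprintf("L%d_b1", l)]])
    Hrelu <- Hpre * (Hpre > 0)
    F2 <- add_cols(Hrelu %*% params[[sprintf("L%d_W2", l)]],
                   params[[sprintf("L%d_b2", l)]])
    mask2 <- NULL
    if (drop_p > 0) {
      mask2 <- matrix((stats::runif(length(F2)) >= drop_p) / (1 - drop_p),
                      nrow(F2), ncol(F2))
      F2 <- F2 * mask2
    }
    X2 <- X1 + F2
    if (keep_cache) {
      cache$layers[[l]] <- list(X_in = X, ln1 = ln1, N1 = N1,
                                Q = Q, K = K, V = V,
                                P_heads = P_heads, Oc = Oc,
                                mask1 = mask1, X1 = X1, ln2 = ln2, N2 = N2,
                                Hpre = Hpre, Hrelu = Hrelu, mask2 = mask2)
    }
    if (collect_attention) attn[[l]] <- P_heads
    X <- X2
  }

  lnf <- layernorm_fwd(X, params$lnf_g, params$lnf_b)
  Z <- lnf$y[cls_rows, , drop = FALSE] # classification-token readout
  logit <- unname(drop(Z %*% params$w_out)) + params$b_out
  prob <- stats::plogis(logit)
  out <- list(prob = prob, logit = logit, Z = Z)
  if (keep_cache) { cache$lnf <- lnf; out$cache <- cache }
  if (collect_attention) out$attn <- attn
  out
}

# Backward pass for mean binary cross-entropy. Returns the gradient list
# (same names/shapes as params).
encoder_backward <- function(params, cfg, fwd, y01) {
  cache <- fwd$cache
  B <- length(y01); C <- length(cache$comp_idx) / B
  d <- cfg$embed_dim; H <- cfg$n_heads; dh <- d / H
  grads <- list()

  dlogit <- (fwd$prob - y01) / B
  grads$w_out <- drop(crossprod(fwd$Z, dlogit))
  grads$b_out <- sum(dlogit)
  dlnf_y <- matrix(0, B * C, d)
  dlnf_y[cache$cls_rows, ] <- outer(dlogit, params$w_out)
  bwf <- layernorm_bwd(dlnf_y, cache$lnf, params$lnf_g)
  grads$lnf_g <- bwf$dg
  grads$lnf_b <- bwf$db
  dX <- bwf$dx

  for (l in rev(seq_len(cfg$n_layers))) {
    cl <- cache$layers[[l]]
    # FFN sublayer: X2 = X1 + dropout(FFN(LN2(X1)))
    dX1 <- dX
    dF2 <- if (is.null(cl$mask2)) dX else dX * cl$mask2
    W2 <- params[[sprintf("L%d_W2", l)]]
    grads[[sprintf("L%d_W2", l)]] <- crossprod(cl$Hrelu, dF2)
    grads[[sprintf("L%d_b2", l)]] <- colSums(dF2)
    dHrelu <- tcrossprod(dF2, W2)
    dHpre <- dHrelu * (cl$Hpre > 0)
    W1 <- params[[sprintf("L%d_W1", l)]]
    grads[[sprintf("L%d_W1", l)]] <- crossprod(cl$N2, dHpre)
    grads[[sprintf("L%d_b1", l)]] <- colSums(dHpre)
    dN2 <- tcrossprod(dHpre, W1)
    g2 <- params[[sprintf("L%d_ln2_g", l)]]
    bw2 <- layernorm_bwd(dN2, cl$ln2, g2)
    grads[[sprintf("L%d_ln2_g", l)]] <- bw2$dg
    grads[[sprintf("L%d_ln2_b", l)]] <- bw2$db
    dX1 <- dX1 + bw2$dx

    # attention sublayer: X1 = X + dropout(Wo * MHSA(LN1(X)))
    dXin <- dX1
    dO2 <- if (is.null(cl$mask1)) dX1 else dX1 * cl$mask1
    Wo <- params[[sprintf("L%d_Wo", l)]]
    grads[[sprintf("L%d_Wo", l)]] <- crossprod(cl$Oc, dO2)
    dOc <- tcrossprod(dO2, Wo)

    bb <- block_attn_bwd(cl$Q, cl$K, cl$V, cl$P_heads, dOc, B, C, H)
    dQ <- bb$dQ; dK <- bb$dK; dV <- bb$dV
    grads[[sprintf("L%d_Wq", l)]] <- crossprod(cl$N1, dQ)
    grads[[sprintf("L%d_Wk", l)]] <- crossprod(cl$N1, dK)
    grads[[sprintf("L%d_Wv", l)]] <- crossprod(cl$N1, dV)
    dN1 <- tcrossprod(dQ, params[[sprintf("L%d_Wq", l)]]) +
      tcrossprod(dK, params[[sprintf("L%d_Wk", l)]]) +
      tcrossprod(dV, params[[sprintf("L%d_Wv", l)]])
    g1 <- params[[sprintf("L%d_ln1_g", l)]]
    bw1 <- layernorm_bwd(dN1, cl$ln1, g1)
    grads[[sprintf("L%d_ln1_g", l)]] <- bw1$dg
    grads[[sprintf("L%d_ln1_b", l)]] <- bw1$db
    dX <- dXin + bw1$dx
  }

  grads$w_embed <- drop(crossprod(dX, cache$s_vec))
  grads$b_embed <- colSums(dX)
  grads$pos <- rowsum(dX, cache$comp_idx)
  grads
}

bce_loss <- function(prob, y01, eps = 1e-12) {
  -mean(y01 * log(prob + eps) + (1 - y01) * log(1 - prob + eps))
}

# evaluation-mode forward in chunks: attention cost is quadratic in
# (chunk size x tokens), so large matrices are predicted piecewise
encoder_predict_chunked <- function(params, S, cfg, chunk = 32L) {
  n <- nrow(S)
  starts <- seq(1, n, by = chunk)
  unlist(lapply(starts, function(s) {
    idx <- s:min(s + chunk - 1, n)
    encoder_forward(params, S[idx, , drop = FALSE], cfg)$prob
  }), use.names = FALSE)
}

# parameters subject to L2 weight decay (weight matrices, not biases,
# layernorm gains/shifts or positional embeddings)
decayed_param <- function(name) {
  grepl("_W[qkvo12]$|^w_embed$|^w_out$", name) | grepl("_W[12]$", name)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L,
       decay = vapply(names(params), decayed_param, logical(1)))
}

adam_step <- function(params, grads, state, cfg) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    # kernels may return vectors as one-column matrices; match param shape
    if (is.null(dim(params[[nm]]))) g <- as.vector(g) else
      dim(g) <- dim(params[[nm]])
    if (cfg$weight_decay > 0 && state$decay[[nm]]) {
      g <- g + cfg$weight_decay * params[[nm]]
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the attention encoder on PC scores
#'
#' Tokenizes each sample's principal-component vector (one token per
#' component, shared scalar-to-`embed_dim` linear embedding plus learned
#' positional embedding), runs it through `n_layers` multi-head
#' self-attention encoder layers, mean-pools the tokens and maps to a
#' sigmoid probability. Optimized with Adam on mean binary cross-entropy
#' with L2 weight decay; training stops when the validation loss fails to
#' improve for `patience` epochs (a stratified 20% split of the training
#' data, falling back to the training loss when a class has fewer than 5
#' samples) or at `max_epochs`. Fully reproducible given `config$seed`.
#'
#' @param train_scores numeric matrix of PC scores (samples x components).
#' @param train_labels binary labels aligned to rows.
#' @param config an [attention_config()].
#' @param val_data optional list `(scores, labels)` to use as the
#'   early-stopping validation set instead of the internal split (used by the
#'   deliberate-leakage mode; with an external set, all training rows are
#'   used for gradient steps).
#' @return An object of class `attn_encoder` with elements `params`,
#'   `config`, `history` (per-epoch train/validation loss), `best_epoch`,
#'   `stopped_epoch`, `n_tokens`.
#' @export
train_encoder <- function(train_scores, train_labels, config, val_data = NULL) {
  y <- as_binary01(train_labels)
  if (!all(is.finite(train_scores))) stop("scores must be finite")
  if (config$embed_dim %% config$n_heads != 0) {
    stop("embed_dim must be divisible by n_heads")
  }
  C <- ncol(train_scores)
  cfg <- config

  # component scores are centred per component and scaled by the leading
  # component's training-set SD before tokenization. A single shared scale
  # keeps the optimizer well-conditioned while preserving the variance
  # hierarchy across components — the magnitude cue that lets the attention
  # single out high-variance informative tokens. The scaler is part of the
  # model, so the confinement to training data is preserved.
  input_scaler <- fit_scaler(train_scores)
  input_scaler$sd <- rep(max(input_scaler$sd), length(input_scaler$sd))
  train_scores <- apply_scaler(train_scores, input_scaler)

  withr::with_seed(cfg$seed, {
    if (!is.null(val_data)) {
      tr_idx <- seq_len(nrow(train_scores))
      val_scores <- apply_scaler(val_data$scores, input_scaler)
      val_y <- as_binary01(val_data$labels)
    } else if (min(table(y)) >= 5) {
      fold <- stratified_folds(y, 5)
      tr_idx <- which(fold != 1)
      val_scores <- train_scores[fold == 1, , drop = FALSE]
      val_y <- y[fold == 1]
    } else {
      tr_idx <- seq_len(nrow(train_scores))
      val_scores <- train_scores
      val_y <- y
    }
    Xtr <- train_scores[tr_idx, , drop = FALSE]
    ytr <- y[tr_idx]

    params <- attn_init_params(C + 1L, cfg) # +1 for the classification token
    state <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())

    n <- nrow(Xtr)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      loss_sum <- 0; loss_n <- 0L
      for (s in starts) {
        b_idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        if (length(b_idx) < 2) next
        n_tok <- length(b_idx) * (C + 1L)
        drop_masks <- lapply(seq_len(cfg$n_layers), function(l) {
          if (cfg$dropout == 0) return(list())
          keep <- 1 - cfg$dropout
          # both masks apply to sublayer outputs, which live in embed_dim
          list(matrix((stats::runif(n_tok * cfg$embed_dim) >= cfg$dropout) / keep,
                      n_tok, cfg$embed_dim),
               matrix((stats::runif(n_tok * cfg$embed_dim) >= cfg$dropout) / keep,
                      n_tok, cfg$embed_dim))
        })
        step <- encoder_step_cpp(params, Xtr[b_idx, , drop = FALSE],
                                 ytr[b_idx], drop_masks,
                                 cfg$n_layers, cfg$n_heads, 0)
        upd <- adam_step(params, step$grads, state, cfg)
        params <- upd$params; state <- upd$state
        loss_sum <- loss_sum + step$loss * length(b_idx)
        loss_n <- loss_n + length(b_idx)
      }
      tr_loss <- loss_sum / loss_n # mean minibatch loss (dropout active)
      val_loss <- bce_loss(encoder_predict_chunked(params, val_scores, cfg), val_y)
      if (!is.finite(tr_loss) || !is.finite(val_loss)) {
        stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
      }
      history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                           val_loss = val_loss))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }

    structure(
      list(params = best$params, config = cfg, history = history,
           best_epoch = best$epoch, stopped_epoch = nrow(history),
           n_tokens = C, input_scaler = input_scaler),
      class = "attn_encoder"
    )
  })
}

#' Predict class probabilities from a trained encoder
#' @param model an `attn_encoder`.
#' @param scores numeric matrix of PC scores (samples x components, same
#'   component count as in training).
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_encoder <- function(model, scores) {
  stopifnot(inherits(model, "attn_encoder"))
  if (ncol(scores) != model$n_tokens) stop("component count mismatch")
  encoder_predict_chunked(model$params,
                          apply_scaler(scores, model$input_scaler),
                          model$config)
}

#' @export
print.attn_encoder <- function(x, ...) {
  cat(sprintf(
    "<attn_encoder> %d layers, %d heads, embed_dim %d; stopped at epoch %d (best %d)\n",
    x$config$n_layers, x$config$n_heads, x$config$embed_dim,
    x$stopped_epoch, x$best_epoch
  ))
  invisible(x)
}
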