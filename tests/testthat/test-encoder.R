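att <- asNamespace("attnomics")

test_that("analytic gradients match finite differences", {
  withr::with_seed(42, {
    cfg <- attention_config("metabolome", n_components = 4, embed_dim = 8,
                            ff_dim = 12, n_layers = 2, n_heads = 2,
                            dropout = 0, seed = 7)
    S <- matrix(rnorm(5 * 4), 5, 4)
    y <- c(0, 1, 0, 1, 1)
    params <- att$attn_init_params(5, cfg) # 4 components + classification token
    fwd <- att$encoder_forward(params, S, cfg, keep_cache = TRUE)
    grads <- att$encoder_backward(params, cfg, fwd, y)

    loss_at <- function(p) att$bce_loss(att$encoder_forward(p, S, cfg)$prob, y)
    eps <- 1e-6
    for (nm in c("w_embed", "pos", "L1_Wq", "L1_Wk", "L2_Wv", "L2_Wo",
                 "L1_ln1_g", "L2_ln2_b", "L2_W2", "L1_b1", "w_out", "b_out")) {
      g <- grads[[nm]]
      for (i in seq_len(min(4, length(g)))) {
        p_hi <- params; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
        p_lo <- params; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
        num <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
        expect_lt(abs(num - g[i]) / max(1e-8, abs(num) + abs(g[i])), 1e-5)
      }
    }
  })
})

test_that("compiled training step agrees with the R reference backward", {
  withr::with_seed(17, {
    cfg <- attention_config("metabolome", n_components = 6, embed_dim = 12,
                            ff_dim = 20, n_layers = 3, n_heads = 3,
                            dropout = 0, seed = 7)
    S <- matrix(rnorm(8 * 6), 8, 6)
    y <- rep(0:1, 4)
    params <- att$attn_init_params(7, cfg)
    fwd <- att$encoder_forward(params, S, cfg, keep_cache = TRUE)
    gR <- att$encoder_backward(params, cfg, fwd, y)
    step <- att$encoder_step_cpp(params, S, y, list(list(), list(), list()),
                                 3L, 3L, 0)
    expect_equal(step$loss, att$bce_loss(fwd$prob, y), tolerance = 1e-12)
    for (nm in names(params)) {
      expect_equal(as.numeric(step$grads[[nm]]), as.numeric(gR[[nm]]),
                   tolerance = 1e-10, label = nm)
    }
  })
})

test_that("training is deterministic given the config seed", {
  withr::with_seed(1, {
    S <- matrix(rnorm(60 * 3), 60, 3)
    y <- rep(0:1, 30)
  })
  cfg <- tiny_attention_config(n_components = 3, seed = 9)
  m1 <- train_encoder(S, y, cfg)
  m2 <- train_encoder(S, y, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_identical(predict_encoder(m1, S), predict_encoder(m2, S))
})

test_that("a linearly separable toy problem is learned", {
  withr::with_seed(3, {
    n <- 120
    y <- rep(0:1, each = n / 2)
    S <- matrix(rnorm(n * 2), n, 2)
    S[, 1] <- S[, 1] + 4 * y
  })
  cfg <- attention_config("metabolome", n_components = 2, seed = 4,
                          max_epochs = 120)
  model <- train_encoder(S, y, cfg)
  acc <- mean((predict_encoder(model, S) >= 0.5) == y)
  expect_gte(acc, 0.95)
})

test_that("permuted labels stall near the chance loss and stop early", {
  withr::with_seed(5, {
    S <- matrix(rnorm(100 * 5), 100, 5)
    y <- sample(rep(0:1, each = 50))
  })
  cfg <- attention_config("metabolome", n_components = 5, seed = 6)
  model <- train_encoder(S, y, cfg)
  expect_lt(model$stopped_epoch, cfg$max_epochs) # early stopping fired
  expect_lt(abs(min(model$history$val_loss) - log(2)), 0.1)
})

test_that("chunked prediction equals single-pass prediction", {
  withr::with_seed(8, {
    S <- matrix(rnorm(50 * 4), 50, 4)
    cfg <- tiny_attention_config(n_components = 4, seed = 2)
    params <- att$attn_init_params(5, cfg) # 4 components + classification token
    p_chunk <- att$encoder_predict_chunked(params, S, cfg, chunk = 7L)
    p_full <- att$encoder_forward(params, S, cfg)$prob
    expect_equal(p_chunk, p_full, tolerance = 1e-12)
  })
})

test_that("non-binary labels and divergence are rejected with diagnostics", {
  S <- matrix(rnorm(30 * 3), 30, 3)
  cfg <- tiny_attention_config(n_components = 3)
  expect_error(train_encoder(S, rep(c("a", "b", "c"), 10), cfg), "binary")
  expect_error(train_encoder(matrix(c(Inf, S[-1])), rep(0:1, 15), cfg),
               "finite")
})
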