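# small fixture builders shared across test files

make_matrix <- function(values, modality = "metabolome", groups = NULL) {
  omics_matrix(values, modality, groups)
}

# two-group matrix with a planted mean shift in the first `n_signal` columns
make_shifted_matrix <- function(n_per_group = 20, p = 20, n_signal = 2,
                                shift = 2, seed = 1,
                                modality = "metabolome") {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%03d", 1:n), sprintf("f%03d", 1:p)))
    g <- factor(rep(c("RA", "RA_ane"), each = n_per_group),
                levels = c("RA", "RA_ane"))
    if (n_signal > 0) {
      x[g == "RA_ane", seq_len(n_signal)] <-
        x[g == "RA_ane", seq_len(n_signal)] + shift
    }
    omics_matrix(x, modality, g, validate = FALSE)
  })
}

apply_scaler_for_test <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

tiny_attention_config <- function(modality = "metabolome", ...) {
  attention_config(modality, embed_dim = 12, ff_dim = 16, n_layers = 2,
                   max_epochs = 40, ...)
}
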