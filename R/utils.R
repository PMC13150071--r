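# internal helpers shared across modules

# Coerce labels to 0/1 with the second factor level (or lexicographically
# larger value) as the positive class. Returns integer vector with a
# "positive" attribute naming the positive level.
as_binary01 <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    y <- as.integer(labels)
    attr(y, "positive") <- "1"
    return(y)
  }
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must be binary (exactly two classes)")
  y <- as.integer(f) - 1L
  attr(y, "positive") <- levels(f)[2]
  y
}

# Stratified k-fold assignment: within each class the fold sizes differ by at
# most one, so overall fold sizes differ by <= 1 per class. Consumes RNG.
stratified_folds <- function(labels, k) {
  y <- as_binary01(labels)
  if (min(table(y)) < k) stop("need at least `k` samples per class")
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Column standardization parameters fit on one matrix, applied to another.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd < .Machine$double.eps] <- 1 # constant columns pass through centred
  list(mean = mu, sd = sd)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer")
  }
  as.integer(seed)
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, offset) {
  (as.integer(seed) * 97L + as.integer(offset)) %% 2147483587L
}
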