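#' Parameters for the synthetic omics generators
#'
#' Bundles the knobs shared by [generate_transcriptome()] and
#' [generate_metabolome()]: cohort size, dimensionality, how many features
#' carry a planted group effect and how large that effect is, the missingness
#' and library-size regimes, and the RNG seed. Defaults describe a mid-scale
#' two-group case-control study (RA vs RA with anemia).
#'
#' @param n_per_group samples per group (positive integer).
#' @param n_features number of features (positive integer).
#' @param n_planted number of truly differential features
#'   (`n_planted <= n_features`).
#' @param effect_log2fc planted log2 fold change for transcriptome counts
#'   (group 2 mean multiplied by `2^effect_log2fc`).
#' @param effect_shift_sd planted metabolite mean shift, in units of the
#'   feature's log-scale SD, applied to group 2.
#' @param missing_rate metabolome missing-completely-at-random rate, in
#'   `[0, 0.5)`.
#' @param high_missing_frac fraction of (non-planted) metabolite features
#'   forced above 20% missingness so the missingness filter is exercised.
#' @param zero_gene_frac fraction of genes drawn at very low abundance so
#'   that most exceed 50% zeros, exercising the zero-row filter.
#' @param dispersion_scale multiplier of the negative-binomial dispersion
#'   trend `phi(mu) = dispersion_scale / mu + 0.01` (> 0).
#' @param libsize_cv coefficient of variation of per-sample library-size
#'   factors (>= 0).
#' @param seed integer RNG seed.
#' @return A list of class `synth_omics_params`.
#' @export
synth_omics_params <- function(n_per_group = 40,
                               n_features = 500,
                               n_planted = 20,
                               effect_log2fc = 2,
                               effect_shift_sd = 1.5,
                               missing_rate = 0.05,
                               high_missing_frac = 0.05,
                               zero_gene_frac = 0.05,
                               dispersion_scale = 2,
                               libsize_cv = 0.2,
                               seed = 1) {
  counts <- c(n_per_group = n_per_group, n_features = n_features,
              n_planted = n_planted)
  if (any(counts != round(counts)) || n_per_group < 1 || n_features < 1 ||
      n_planted < 0) {
    stop("n_per_group, n_features, n_planted must be non-negative integers (counts positive)")
  }
  if (n_planted > n_features) stop("n_planted must not exceed n_features")
  if (missing_rate < 0 || missing_rate >= 0.5) stop("missing_rate must lie in [0, 0.5)")
  if (high_missing_frac < 0 || high_missing_frac > 1) stop("high_missing_frac must lie in [0, 1]")
  if (zero_gene_frac < 0 || zero_gene_frac > 1) stop("zero_gene_frac must lie in [0, 1]")
  if (dispersion_scale <= 0) stop("dispersion_scale must be > 0")
  if (libsize_cv < 0) stop("libsize_cv must be >= 0")
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_features = as.integer(n_features),
         n_planted = as.integer(n_planted),
         effect_log2fc = effect_log2fc,
         effect_shift_sd = effect_shift_sd,
         missing_rate = missing_rate,
         high_missing_frac = high_missing_frac,
         zero_gene_frac = zero_gene_frac,
         dispersion_scale = dispersion_scale,
         libsize_cv = libsize_cv,
         seed = check_seed(seed)),
    class = "synth_omics_params"
  )
}

synth_groups <- function(n_per_group) {
  factor(rep(c("RA", "RA_ane"), each = n_per_group), levels = c("RA", "RA_ane"))
}

#' Synthetic RNA-seq count matrix with planted fold changes
#'
#' Gene-wise baseline means are log-normal; counts are negative-binomial with
#' the dispersion trend `phi(mu) = dispersion_scale / mu + 0.01` (dispersion
#' decreasing in the mean, as in bulk RNA-seq); per-sample library sizes are
#' log-normal with coefficient of variation `libsize_cv`; a configurable
#' fraction of genes is drawn at very low abundance so that they exceed 50%
#' zeros. Planted genes have their group-2 mean multiplied by
#' `2^effect_log2fc`. Identical parameters (including seed) give identical
#' output.
#'
#' @param params a [synth_omics_params()] object.
#' @return A list with elements `matrix` (a transcriptome `omics_matrix` with
#'   group labels) and `truth` (a list with `planted_feature_ids`,
#'   `effect` — per-feature true log2 fold change, 0 for non-planted — and
#'   `group_assignment`).
#' @export
generate_transcriptome <- function(params) {
  stopifnot(inherits(params, "synth_omics_params"))
  withr::with_seed(params$seed, {
    n <- 2L * params$n_per_group
    p <- params$n_features
    genes <- sprintf("gene_%04d", seq_len(p))
    groups <- synth_groups(params$n_per_group)

    base_mu <- stats::rlnorm(p, meanlog = log(80), sdlog = 1.4)
    n_low <- round(params$zero_gene_frac * p)
    low_idx <- if (n_low > 0) sample.int(p, n_low) else integer(0)
    base_mu[low_idx] <- stats::runif(n_low, 0.02, 0.3)

    eligible <- setdiff(seq_len(p), low_idx)
    planted <- sort(sample(eligible, params$n_planted))
    effect <- numeric(p)
    effect[planted] <- params$effect_log2fc

    sf <- if (params$libsize_cv > 0) {
      s <- sqrt(log(1 + params$libsize_cv^2))
      stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
    } else rep(1, n)

    mu_g1 <- base_mu
    mu_g2 <- base_mu * 2^effect
    counts <- matrix(0L, n, p, dimnames = list(sprintf("S%03d", seq_len(n)), genes))
    for (j in seq_len(p)) {
      mu_j <- ifelse(groups == "RA_ane", mu_g2[j], mu_g1[j]) * sf
      phi <- params$dispersion_scale / ((mu_g1[j] + mu_g2[j]) / 2) + 0.01
      counts[, j] <- stats::rnbinom(n, mu = mu_j, size = 1 / phi)
    }
    storage.mode(counts) <- "integer"

    list(
      matrix = omics_matrix(counts, "transcriptome", groups),
      truth = list(planted_feature_ids = genes[planted],
                   effect = stats::setNames(effect, genes),
                   group_assignment = groups)
    )
  })
}

#' Synthetic metabolite intensity matrix with planted shifts
#'
#' Feature-wise log-normal intensities on the raw scale (so sum
#' normalization and log10 transformation downstream are exercised), strictly
#' positive before masking. An MCAR mask is applied at `missing_rate`, and a
#' configurable set of non-planted features is masked above 20% to exercise
#' the missingness filter. Planted features have their group-2 log-scale mean
#' shifted by `effect_shift_sd` feature SDs.
#'
#' @inheritParams generate_transcriptome
#' @return A list with `matrix` (metabolome `omics_matrix`, `NA` = missing)
#'   and `truth` (as in [generate_transcriptome()], `effect` in SD units).
#' @export
generate_metabolome <- function(params) {
  stopifnot(inherits(params, "synth_omics_params"))
  withr::with_seed(params$seed, {
    n <- 2L * params$n_per_group
    p <- params$n_features
    mets <- sprintf("met_%04d", seq_len(p))
    groups <- synth_groups(params$n_per_group)

    meanlog <- stats::rnorm(p, mean = log(1e5), sd = 1)
    sdlog <- stats::runif(p, 0.25, 0.6)

    n_high <- round(params$high_missing_frac * p)
    planted <- sort(sample.int(p, params$n_planted))
    high_pool <- setdiff(seq_len(p), planted)
    high_idx <- if (n_high > 0) sample(high_pool, min(n_high, length(high_pool))) else integer(0)

    effect <- numeric(p)
    effect[planted] <- params$effect_shift_sd

    x <- matrix(NA_real_, n, p, dimnames = list(sprintf("S%03d", seq_len(n)), mets))
    g2 <- groups == "RA_ane"
    for (j in seq_len(p)) {
      ml <- rep(meanlog[j], n)
      ml[g2] <- ml[g2] + effect[j] * sdlog[j]
      x[, j] <- stats::rlnorm(n, meanlog = ml, sdlog = sdlog[j])
    }

    if (params$missing_rate > 0) {
      mask <- matrix(stats::runif(n * p) < params$missing_rate, n, p)
      x[mask] <- NA_real_
    }
    # force selected features above the 20% missingness threshold
    for (j in high_idx) {
      k <- ceiling(0.3 * n)
      x[sample.int(n, k), j] <- NA_real_
    }

    list(
      matrix = omics_matrix(x, "metabolome", groups),
      truth = list(planted_feature_ids = mets[planted],
                   effect = stats::setNames(effect, mets),
                   group_assignment = groups)
    )
  })
}

#' Synthetic clinical covariate table with a planted HB-inflammation link
#'
#' Draws age, sex, disease duration, a 3-level treatment class and four
#' inflammatory markers (ESR, CRP, IL-6, DAS28, mutually correlated through a
#' latent inflammation factor), then builds hemoglobin as a linear function of
#' the standardized markers plus covariate terms and Gaussian noise:
#' `HB = 130 + beta_esr * z(ESR) + beta_crp * z(CRP) - 0.15 * z(age)
#'  - 1.5 * I(female) + small duration/treatment terms + N(0, noise_sd)`.
#' Effects are expressed per marker SD on a unit-noise hemoglobin scale, so
#' planted coefficients are directly recoverable by [hb_association()].
#'
#' @param n number of patients (>= 10).
#' @param seed integer RNG seed.
#' @param beta_esr,beta_crp planted coefficients (negative by default).
#' @param noise_sd residual SD of HB (> 0).
#' @return A `data.frame` with columns `sample_id`, `age`, `sex`,
#'   `disease_duration`, `treatment`, `HB`, `CRP`, `ESR`, `IL6`, `DAS28`.
#' @export
generate_clinical <- function(n, seed = 1, beta_esr = -0.4, beta_crp = -0.25,
                              noise_sd = 0.9) {
  if (n < 10) stop("n must be >= 10")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  withr::with_seed(check_seed(seed), {
    age <- pmax(18, round(stats::rnorm(n, 56, 12)))
    sex <- factor(ifelse(stats::runif(n) < 0.78, "female", "male"),
                  levels = c("male", "female"))
    duration <- round(stats::rexp(n, rate = 1 / 5), 1)
    treatment <- factor(sample(c("none", "csDMARD", "biologic"), n,
                               replace = TRUE, prob = c(0.2, 0.5, 0.3)),
                        levels = c("none", "csDMARD", "biologic"))

    f <- stats::rnorm(n) # latent inflammation factor
    z_esr <- 0.7 * f + sqrt(1 - 0.49) * stats::rnorm(n)
    z_crp <- 0.7 * f + sqrt(1 - 0.49) * stats::rnorm(n)
    z_il6 <- 0.6 * f + 0.8 * stats::rnorm(n)
    z_das <- 0.5 * f + sqrt(0.75) * stats::rnorm(n)

    hb <- 130 +
      beta_esr * z_esr + beta_crp * z_crp -
      0.15 * scale(age)[, 1] - 1.5 * (sex == "female") +
      0.05 * scale(duration)[, 1] +
      c(none = 0, csDMARD = 0.1, biologic = -0.1)[as.character(treatment)] +
      stats::rnorm(n, sd = noise_sd)

    data.frame(
      sample_id = sprintf("P%04d", seq_len(n)),
      age = age, sex = sex, disease_duration = duration,
      treatment = treatment,
      HB = as.numeric(hb),
      CRP = exp(2.2 + 0.9 * z_crp),
      ESR = 40 + 22 * z_esr, # left unclipped so HB is exactly linear in z(ESR)
      IL6 = exp(1.5 + 0.8 * z_il6),
      DAS28 = pmin(9.4, pmax(0, 4 + 1.2 * z_das)),
      stringsAsFactors = FALSE
    )
  })
}

#' Synthetic visit-level hospital records for incidence analysis
#'
#' For each year and cohort draws Bernoulli anemia outcomes at the stated
#' rate and then realizes them as hemoglobin values consistent with the
#' sex-specific anemia thresholds (<120 g/l male, <110 g/l female), so that
#' [annual_incidence()] recovers the planted rates from raw records.
#'
#' @param years integer vector of calendar years.
#' @param rates_by_cohort named list (one element per cohort) of per-year
#'   anemia rates in `[0, 1]`, each the same length as `years`.
#' @param n_by_cohort named list of per-year cohort sizes (positive
#'   integers), same shape as `rates_by_cohort`.
#' @param seed integer RNG seed.
#' @param female_frac named vector of female fraction per cohort (default
#'   0.5 for every cohort).
#' @return A `data.frame` with columns `individual_id`, `year`, `cohort`,
#'   `sex`, `HB`.
#' @export
generate_incidence <- function(years, rates_by_cohort, n_by_cohort, seed = 1,
                               female_frac = NULL) {
  if (!identical(sort(names(rates_by_cohort)), sort(names(n_by_cohort)))) {
    stop("rates_by_cohort and n_by_cohort must have the same cohort names")
  }
  for (ch in names(rates_by_cohort)) {
    if (length(rates_by_cohort[[ch]]) != length(years) ||
        length(n_by_cohort[[ch]]) != length(years)) {
      stop("per-cohort rates and sizes must match the number of years")
    }
    if (any(rates_by_cohort[[ch]] < 0 | rates_by_cohort[[ch]] > 1)) {
      stop("rates must lie in [0, 1]")
    }
    if (any(n_by_cohort[[ch]] < 1)) stop("cohort sizes must be positive")
  }
  if (is.null(female_frac)) {
    female_frac <- stats::setNames(rep(0.5, length(rates_by_cohort)),
                                   names(rates_by_cohort))
  }
  withr::with_seed(check_seed(seed), {
    out <- list()
    uid <- 0L
    for (ch in names(rates_by_cohort)) {
      for (i in seq_along(years)) {
        n <- n_by_cohort[[ch]][i]
        rate <- rates_by_cohort[[ch]][i]
        anemic <- stats::runif(n) < rate
        sex <- ifelse(stats::runif(n) < female_frac[[ch]], "female", "male")
        thr <- ifelse(sex == "male", 120, 110)
        hb <- ifelse(anemic,
                     thr - stats::runif(n, 1, 30),
                     thr + stats::runif(n, 0, 40))
        out[[length(out) + 1L]] <- data.frame(
          individual_id = sprintf("%s_%d_%06d", ch, years[i], uid + seq_len(n)),
          year = years[i], cohort = ch, sex = sex, HB = round(hb, 1),
          stringsAsFactors = FALSE
        )
        uid <- uid + n
      }
    }
    do.call(rbind, out)
  })
}
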