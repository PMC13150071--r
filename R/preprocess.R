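#' Drop metabolite features with excessive missingness
#'
#' Removes features whose fraction of missing values is strictly greater
#' than `max_missing_frac` (default: strictly more than 20% missing).
#' Retained features keep their original order.
#'
#' @param m a metabolome `omics_matrix`.
#' @param max_missing_frac maximum tolerated missing fraction (strict `>`
#'   removal).
#' @return The filtered `omics_matrix`, with attribute `removed` listing the
#'   dropped feature ids.
#' @export
filter_metabolite_missingness <- function(m, max_missing_frac = 0.20) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$modality != "metabolome") stop("missingness filter applies to metabolome matrices")
  frac <- colMeans(is.na(m$values))
  keep <- frac <= max_missing_frac
  if (!any(keep)) stop("all features exceed the missingness threshold; nothing left")
  out <- omics_matrix(m$values[, keep, drop = FALSE], m$modality, m$groups)
  attr(out, "removed") <- colnames(m$values)[!keep]
  out
}

#' Impute missing intensities with the per-feature minimum
#'
#' Each missing entry is replaced by the minimum observed value of its
#' feature, mirroring the convention that missingness reflects values below
#' the detection floor.
#'
#' @param m a metabolome `omics_matrix`.
#' @return An `omics_matrix` with no missing values.
#' @export
impute_min <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  x <- m$values
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0)) {
    stop("feature(s) with zero observed values cannot be imputed: ",
         paste(utils::head(colnames(x)[n_obs == 0], 5), collapse = ", "))
  }
  for (j in which(colSums(is.na(x)) > 0)) {
    x[is.na(x[, j]), j] <- min(x[, j], na.rm = TRUE)
  }
  omics_matrix(x, m$modality, m$groups)
}

#' Sum normalization followed by log10 transformation
#'
#' Divides each sample's intensities by the sample total, multiplies by a
#' fixed constant (10^4) and applies log10. Back-transformed rows therefore
#' sum exactly to the constant, and the transform is invariant to per-sample
#' positive rescaling of the input.
#'
#' @param m an `omics_matrix` with strictly positive values (after
#'   imputation), or non-negative if `pseudocount > 0`.
#' @param pseudocount added to every value before normalization (default 0).
#' @param constant the per-sample total after normalization (default `1e4`).
#' @return The transformed `omics_matrix` (log10 scale).
#' @export
sum_normalize_log10 <- function(m, pseudocount = 0, constant = 1e4) {
  stopifnot(inherits(m, "omics_matrix"))
  x <- m$values + pseudocount
  if (anyNA(x)) stop("missing values present; impute before normalizing")
  if (any(x <= 0)) stop("values must be strictly positive (use a pseudocount)")
  totals <- rowSums(x)
  x <- log10(x / totals * constant)
  omics_matrix(x, m$modality, m$groups)
}

#' Drop genes with excessive zero counts
#'
#' Removes genes whose fraction of zero counts is strictly greater than
#' `max_zero_frac` (default: strictly more than 50% zeros).
#'
#' @param m a transcriptome `omics_matrix`.
#' @param max_zero_frac maximum tolerated zero fraction (strict `>` removal).
#' @return The filtered `omics_matrix`, with attribute `removed`.
#' @export
filter_zero_rows <- function(m, max_zero_frac = 0.50) {
  stopifnot(inherits(m, "omics_matrix"))
  if (m$modality != "transcriptome") stop("zero-row filter applies to transcriptome matrices")
  frac <- colMeans(m$values == 0)
  keep <- frac <= max_zero_frac
  if (!any(keep)) stop("all genes exceed the zero-count threshold; nothing left")
  out <- omics_matrix(m$values[, keep, drop = FALSE], m$modality, m$groups)
  attr(out, "removed") <- colnames(m$values)[!keep]
  out
}

#' Median-of-ratios size factors
#'
#' The count-normalization estimator popularized by DESeq: for each sample,
#' the size factor is the median over reference genes (genes with nonzero
#' counts in every sample) of the ratio of the sample's count to the gene's
#' geometric mean across samples.
#'
#' @param m a transcriptome `omics_matrix`.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors_median_of_ratios <- function(m) {
  stopifnot(inherits(m, "omics_matrix"), m$modality == "transcriptome")
  counts <- m$values
  all_pos <- colSums(counts == 0) == 0
  if (!any(all_pos)) stop("no gene has nonzero counts in all samples")
  logc <- log(counts[, all_pos, drop = FALSE])
  geo <- colMeans(logc) # log geometric mean per reference gene
  sf <- apply(logc, 1, function(row) exp(stats::median(row - geo)))
  stats::setNames(sf, rownames(counts))
}
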