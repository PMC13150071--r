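#' Sample-by-feature omics matrix
#'
#' Lightweight container used throughout the package: a numeric matrix with
#' samples as rows and features as columns, a modality tag, and optional
#' binary group labels aligned to the rows. Metabolite matrices may carry
#' `NA` for undetected intensities; transcriptome matrices must hold
#' non-negative integer counts.
#'
#' @param values numeric matrix, samples x features, with row and column names.
#' @param modality one of `"metabolome"`, `"transcriptome"`, `"proteome"`.
#' @param groups optional factor/character vector of length `nrow(values)`
#'   with exactly two levels (second level is the positive class, e.g.
#'   `"RA_ane"`).
#' @param validate check modality-specific value constraints (set to `FALSE`
#'   for derived matrices, e.g. log-normalized counts that are no longer
#'   integers).
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values,
                         modality = c("metabolome", "transcriptome", "proteome"),
                         groups = NULL, validate = TRUE) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%04d", seq_len(ncol(values)))
  }
  if (modality == "transcriptome" && validate) {
    if (anyNA(values)) stop("transcriptome counts must not contain NA")
    if (any(values < 0) || any(values != round(values))) {
      stop("transcriptome values must be non-negative integers")
    }
  }
  if (!is.null(groups)) {
    if (length(groups) != nrow(values)) {
      stop("`groups` must have one entry per sample")
    }
    groups <- as.factor(groups)
    if (nlevels(groups) != 2) stop("`groups` must have exactly two levels")
  }
  structure(
    list(values = values, modality = modality, groups = groups),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix> %s: %d samples x %d features\n",
    x$modality, nrow(x$values), ncol(x$values)
  ))
  if (!is.null(x$groups)) {
    tb <- table(x$groups)
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  na_frac <- mean(is.na(x$values))
  if (na_frac > 0) cat(sprintf("  missing: %.1f%%\n", 100 * na_frac))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Feature identifiers of an omics matrix
#' @param m an `omics_matrix`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(m) colnames(m$values)

#' Sample identifiers of an omics matrix
#' @param m an `omics_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(m) rownames(m$values)

#' Restrict an omics matrix to a feature subset
#' @param m an `omics_matrix`.
#' @param features character vector of feature ids (order preserved as given).
#' @return An `omics_matrix` with only the requested features.
#' @export
subset_features <- function(m, features) {
  missing <- setdiff(features, feature_ids(m))
  if (length(missing) > 0) {
    stop("unknown feature ids: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  omics_matrix(m$values[, features, drop = FALSE], m$modality, m$groups,
               validate = FALSE)
}

#' Write / read an omics matrix as TSV
#'
#' Samples as rows, features as columns, first column `sample_id`. Missing
#' values are written as empty fields.
#'
#' @param m an `omics_matrix`.
#' @param path file path.
#' @rdname omics_tsv
#' @return `write_omics_tsv` returns `path` invisibly; `read_omics_tsv`
#'   returns an `omics_matrix`.
#' @export
write_omics_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @param modality modality tag for the matrix being read.
#' @param groups optional group labels for the samples being read.
#' @rdname omics_tsv
#' @export
read_omics_tsv <- function(path, modality, groups = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  storage.mode(values) <- if (modality == "transcriptome") "integer" else "double"
  omics_matrix(values, modality, groups)
}

#' Write / read sample group labels as TSV
#'
#' Two columns: `sample_id`, `group`.
#'
#' @param sample_ids character vector.
#' @param groups factor/character vector aligned to `sample_ids`.
#' @param path file path.
#' @rdname labels_tsv
#' @return `read_labels_tsv` returns a named factor (names = sample ids).
#' @export
write_labels_tsv <- function(sample_ids, groups, path) {
  utils::write.table(
    data.frame(sample_id = sample_ids, group = as.character(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname labels_tsv
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(factor(df$group), df$sample_id)
}
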