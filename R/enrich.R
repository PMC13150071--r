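#' Read gene/metabolite sets from a GMT file
#'
#' Tab-separated dialect: set id, description, then member ids. Duplicate
#' members within a line are deduplicated; empty sets are dropped with a
#' warning.
#'
#' @param path GMT file path.
#' @return A list of class `annotation_sets`: `sets` (named list of member
#'   vectors), `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descr <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop(sprintf("malformed GMT line %d (need >= 3 columns)", i))
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      warning("dropping empty set: ", parts[1])
      next
    }
    sets[[parts[1]]] <- members
    descr[parts[1]] <- parts[2]
  }
  structure(list(sets = sets, descriptions = descr), class = "annotation_sets")
}

#' Write annotation sets to a GMT file
#' @param x an `annotation_sets` object (or plain named list of vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  sets <- if (inherits(x, "annotation_sets")) x$sets else x
  descr <- if (inherits(x, "annotation_sets")) x$descriptions else
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descr[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tail `P(X >= k)` for the overlap of the
#' selected features with each annotation set, restricted to the given
#' universe, with BH-FDR across sets.
#'
#' @param selected character vector of selected feature ids (non-empty,
#'   must be a subset of `universe`).
#' @param sets an `annotation_sets` object or named list of member vectors
#'   (members outside the universe are ignored).
#' @param universe character vector of background feature ids (e.g. all
#'   features surviving preprocessing).
#' @return A `data.frame` with `set_id`, `k` (overlap), `K` (set size in
#'   universe), `n` (selected size), `N` (universe size), `p`, `fdr`,
#'   ordered by p.
#' @export
hypergeom_ora <- function(selected, sets, universe) {
  if (length(selected) == 0) stop("empty selection")
  if (length(setdiff(selected, universe)) > 0) {
    stop("selected features must be a subset of the universe")
  }
  set_list <- if (inherits(sets, "annotation_sets")) sets$sets else sets
  N <- length(unique(universe))
  n <- length(unique(selected))
  rows <- lapply(names(set_list), function(id) {
    members <- intersect(set_list[[id]], universe)
    K <- length(members)
    k <- length(intersect(selected, members))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$p)
  res <- res[order(res$p, res$set_id), ]
  rownames(res) <- NULL
  res
}
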