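# Fold-enrichment filtering and two-condition target-set comparison.

#' Filter peaks by fold enrichment
#'
#' Retains exactly the peaks with `fold_enrichment >= min_fold`, preserving
#' input order.
#'
#' @param x A `peaks` table.
#' @param min_fold Non-negative threshold (default 2.0).
#' @return The filtered `peaks` table.
#' @export
filter_peaks_by_fold <- function(x, min_fold = 2.0) {
  stopifnot(inherits(x, "peaks"))
  check_number(min_fold, "min_fold", min = 0)
  out <- x[x$fold_enrichment >= min_fold, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peaks", "data.frame")
  out
}

#' Target-gene set of an annotated condition
#'
#' The target set of a condition is the set of distinct `gene_id`s over its
#' peak annotations with an assigned gene (multiple peaks per gene collapse
#' to one target).
#'
#' @param annotations A `peak_annotation` table.
#' @return Sorted character vector of gene identifiers.
#' @export
target_genes <- function(annotations) {
  stopifnot(inherits(annotations, "peak_annotation"))
  sort(unique(annotations$gene_id[!is.na(annotations$gene_id)]))
}

#' Compare target-gene sets between two conditions
#'
#' Standard common/unique decomposition of two gene-identifier sets
#' (case-sensitive exact match after stripping surrounding whitespace;
#' duplicates collapse).
#'
#' @param targets_a,targets_b Character vectors of gene identifiers.
#' @return A `target_comparison` list: `common`, `unique_a`, `unique_b`
#'   (sorted character vectors) and `counts` (named integer vector).
#' @export
compare_targets <- function(targets_a, targets_b) {
  a <- unique(trimws(as.character(targets_a)))
  b <- unique(trimws(as.character(targets_b)))
  a <- a[nzchar(a)]; b <- b[nzchar(b)]
  common <- sort(intersect(a, b))
  unique_a <- sort(setdiff(a, b))
  unique_b <- sort(setdiff(b, a))
  structure(list(
    common = common, unique_a = unique_a, unique_b = unique_b,
    counts = c(common = length(common), unique_a = length(unique_a),
               unique_b = length(unique_b))
  ), class = "target_comparison")
}

#' @export
print.target_comparison <- function(x, ...) {
  cat(sprintf(
    "<target_comparison> common: %d, unique A: %d, unique B: %d\n",
    x$counts[["common"]], x$counts[["unique_a"]], x$counts[["unique_b"]]))
  invisible(x)
}
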