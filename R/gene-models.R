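# Gene models: strand-aware transcript structures with derived components.

#' Construct a gene-model table
#'
#' Gene models are stored as a data frame with one row per transcript/gene
#' record and list-columns for exon boundaries.  Coordinates are 0-based
#' half-open.  The strand-aware TSS is `tx_start` on `+` and `tx_end - 1` on
#' `-`.  CDS bounds may be `NA` (non-coding record).
#'
#' @param gene_id Character vector of identifiers.
#' @param chrom Character vector of chromosome names.
#' @param strand Character vector, `"+"` or `"-"`.
#' @param tx_start,tx_end Integer vectors, transcript span.
#' @param cds_start,cds_end Integer vectors or `NA` for non-coding records.
#' @param exon_starts,exon_ends Lists of integer vectors (sorted,
#'   non-overlapping, contained in the transcript span).
#' @return A `gene_models` data frame with a `tss` column.
#' @export
gene_models <- function(gene_id, chrom, strand, tx_start, tx_end,
                        cds_start = NA_integer_, cds_end = NA_integer_,
                        exon_starts = NULL, exon_ends = NULL) {
  n <- length(gene_id)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  tx_start <- as.integer(tx_start); tx_end <- as.integer(tx_end)
  cds_start <- rep_len(as.integer(cds_start), n)
  cds_end <- rep_len(as.integer(cds_end), n)
  if (is.null(exon_starts)) exon_starts <- as.list(tx_start)
  if (is.null(exon_ends)) exon_ends <- as.list(tx_end)
  stopifnot(length(chrom) == n, length(strand) == n,
            length(tx_start) == n, length(tx_end) == n,
            length(exon_starts) == n, length(exon_ends) == n)
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  for (i in seq_len(n)) {
    es <- as.integer(exon_starts[[i]]); ee <- as.integer(exon_ends[[i]])
    ok <- length(es) == length(ee) && length(es) >= 1L &&
      all(es < ee) && !is.unsorted(es, strictly = TRUE) &&
      all(es[-1] >= ee[-length(ee)]) &&
      es[1] >= tx_start[i] && ee[length(ee)] <= tx_end[i] &&
      tx_start[i] < tx_end[i]
    if (!ok) {
      stop(sprintf("invalid exon structure for record '%s'", gene_id[i]),
           call. = FALSE)
    }
    if (!is.na(cds_start[i]) &&
        (cds_start[i] < tx_start[i] || cds_end[i] > tx_end[i] ||
         cds_start[i] >= cds_end[i])) {
      stop(sprintf("CDS outside transcript for record '%s'", gene_id[i]),
           call. = FALSE)
    }
    exon_starts[[i]] <- es; exon_ends[[i]] <- ee
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    strand = strand,
                    tx_start = tx_start, tx_end = tx_end,
                    cds_start = cds_start, cds_end = cds_end,
                    stringsAsFactors = FALSE)
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  out$tss <- ifelse(out$strand == "+", out$tx_start, out$tx_end - 1L)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Strand-aware transcription start sites
#' @param genes A `gene_models` table.
#' @return Named integer vector of TSS positions (0-based).
#' @export
tss <- function(genes) {
  stopifnot(inherits(genes, "gene_models"))
  setNames(genes$tss, genes$gene_id)
}

#' Read gene models from BED12 or minimal GTF
#'
#' The BED12 dialect reconstructs exon blocks from `blockSizes`/`blockStarts`
#' and takes CDS bounds from `thickStart`/`thickEnd` (equal values mean
#' non-coding).  The GTF dialect is deliberately minimal: only `exon`
#' features are used and records are grouped by the `gene_id` attribute
#' (CDS/UTR features are ignored, so GTF-derived models are non-coding).
#' Records that violate the gene-model invariants are rejected; the number of
#' rejected records is reported via a warning and the `n_rejected` attribute,
#' never silently dropped.
#'
#' @param path Input file.
#' @param dialect `"bed12"` or `"gtf"`.
#' @return A `gene_models` table with attribute `n_rejected`.
#' @export
read_gene_models <- function(path, dialect = c("bed12", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("gene model file not found: ", path,
                               call. = FALSE)
  if (dialect == "bed12") read_gene_models_bed12(path)
  else read_gene_models_gtf(path)
}

read_gene_models_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  n_in <- length(lines)
  recs <- vector("list", n_in)
  n_rejected <- 0L
  for (i in seq_len(n_in)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) {
      stop(sprintf("BED12 line %d: expected 12 columns, got %d", i,
                   length(f)), call. = FALSE)
    }
    if (!f[6] %in% c("+", "-")) {
      stop(sprintf("BED12 line %d: unknown strand symbol '%s'", i, f[6]),
           call. = FALSE)
    }
    start <- as.integer(f[2]); end <- as.integer(f[3])
    n_blocks <- as.integer(f[10])
    sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", f[12]), ",")[[1]])
    if (length(sizes) != n_blocks || length(offs) != n_blocks) {
      stop(sprintf(
        "BED12 line %d: blockCount %d does not match blockSizes/blockStarts",
        i, n_blocks), call. = FALSE)
    }
    thick_start <- as.integer(f[7]); thick_end <- as.integer(f[8])
    coding <- !is.na(thick_start) && !is.na(thick_end) &&
      thick_start < thick_end
    rec <- tryCatch(
      gene_models(gene_id = f[4], chrom = f[1], strand = f[6],
                  tx_start = start, tx_end = end,
                  cds_start = if (coding) thick_start else NA_integer_,
                  cds_end = if (coding) thick_end else NA_integer_,
                  exon_starts = list(start + offs),
                  exon_ends = list(start + offs + sizes)),
      error = function(e) NULL)
    if (is.null(rec)) n_rejected <- n_rejected + 1L else recs[[i]] <- rec
  }
  finish_gene_models(recs, n_in, n_rejected)
}

read_gene_models_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  exons <- list()  # gene_id -> list(chrom, strand, starts, ends)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      stop(sprintf("GTF line %d: expected 9 columns, got %d", i, length(f)),
           call. = FALSE)
    }
    if (f[3] != "exon") next
    if (!f[7] %in% c("+", "-")) {
      stop(sprintf("GTF line %d: unknown strand symbol '%s'", i, f[7]),
           call. = FALSE)
    }
    m <- regmatches(f[9], regexec("gene_id[ =]+\"?([^\";]+)\"?", f[9]))[[1]]
    if (length(m) < 2L) {
      stop(sprintf("GTF line %d: missing gene_id attribute", i),
           call. = FALSE)
    }
    gid <- m[2]
    start <- as.integer(f[4]) - 1L  # GTF is 1-based closed
    end <- as.integer(f[5])
    if (is.null(exons[[gid]])) {
      exons[[gid]] <- list(chrom = f[1], strand = f[7],
                           starts = integer(0), ends = integer(0))
    }
    exons[[gid]]$starts <- c(exons[[gid]]$starts, start)
    exons[[gid]]$ends <- c(exons[[gid]]$ends, end)
  }
  n_in <- length(exons)
  n_rejected <- 0L
  recs <- vector("list", n_in)
  for (i in seq_along(exons)) {
    e <- exons[[i]]
    ord <- order(e$starts)
    rec <- tryCatch(
      gene_models(gene_id = names(exons)[i], chrom = e$chrom,
                  strand = e$strand,
                  tx_start = min(e$starts), tx_end = max(e$ends),
                  exon_starts = list(e$starts[ord]),
                  exon_ends = list(e$ends[ord])),
      error = function(err) NULL)
    if (is.null(rec)) n_rejected <- n_rejected + 1L else recs[[i]] <- rec
  }
  finish_gene_models(recs, n_in, n_rejected)
}

finish_gene_models <- function(recs, n_in, n_rejected) {
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) stop("no valid gene models loaded", call. = FALSE)
  out <- do.call(rbind, recs)
  class(out) <- c("gene_models", "data.frame")
  rownames(out) <- NULL
  if (n_rejected > 0L) {
    warning(sprintf("%d of %d gene-model record(s) rejected", n_rejected,
                    n_in), call. = FALSE)
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write gene models to BED12
#'
#' Non-coding records are written with `thickStart == thickEnd == tx_start`.
#'
#' @param genes A `gene_models` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    coding <- !is.na(genes$cds_start[i])
    paste(genes$chrom[i], genes$tx_start[i], genes$tx_end[i],
          genes$gene_id[i], 0L, genes$strand[i],
          if (coding) genes$cds_start[i] else genes$tx_start[i],
          if (coding) genes$cds_end[i] else genes$tx_start[i],
          "0", length(es),
          paste0(paste(ee - es, collapse = ","), ","),
          paste0(paste(es - genes$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
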