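# Peak calls: BED / narrowPeak input, validation, anchors.

#' Construct a peak table
#'
#' Peaks are genomic intervals (0-based half-open) with an optional summit
#' offset and a fold-enrichment score.  The derived `anchor` is the single-bp
#' point used by all downstream assignment and scanning steps: the summit
#' when available, otherwise the interval midpoint.
#'
#' @param chrom Character vector.
#' @param start,end Integer vectors, `start < end`.
#' @param name Peak names; autogenerated when `NULL`.
#' @param fold_enrichment Non-negative numeric (default 0).
#' @param summit Integer offsets from `start`, or `NA` (midpoint fallback).
#' @return A `peaks` data frame with an `anchor` column.
#' @export
peaks <- function(chrom, start, end, name = NULL, fold_enrichment = 0,
                  summit = NA_integer_) {
  start <- as.integer(start); end <- as.integer(end)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  fold_enrichment <- rep_len(as.numeric(fold_enrichment), n)
  summit <- rep_len(as.integer(summit), n)
  stopifnot(length(start) == n, length(end) == n, length(name) == n)
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("peak %d ('%s'): start >= end (%d >= %d)", bad[1],
                 name[bad[1]], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  if (any(fold_enrichment < 0, na.rm = TRUE)) {
    stop("fold_enrichment must be non-negative", call. = FALSE)
  }
  bad <- which(!is.na(summit) & (summit < 0L | summit >= end - start))
  if (length(bad)) {
    stop(sprintf("peak %d ('%s'): summit offset %d outside [0, %d)", bad[1],
                 name[bad[1]], summit[bad[1]], end[bad[1]] - start[bad[1]]),
         call. = FALSE)
  }
  anchor <- ifelse(is.na(summit),
                   as.integer((start + end) %/% 2L),
                   start + summit)
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    name = as.character(name),
                    fold_enrichment = fold_enrichment,
                    summit = summit, anchor = as.integer(anchor),
                    stringsAsFactors = FALSE)
  class(out) <- c("peaks", "data.frame")
  out
}

#' Read peaks from BED or narrowPeak
#'
#' Accepts any tab-separated peak file with at least chrom/start/end.  When
#' present, column 7 (narrowPeak `signalValue`) is read as fold enrichment
#' and column 10 as the summit offset from `start` (a negative value, the
#' narrowPeak "no summit" sentinel, becomes `NA` and the anchor falls back to
#' the midpoint).  Malformed rows raise format errors carrying the line
#' number; nothing is silently dropped.
#'
#' @param path Input file.
#' @return A `peaks` table.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  idx <- which(keep)
  if (!length(idx)) stop("no peak records in ", path, call. = FALSE)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop(sprintf("peak file line %d: fewer than 3 columns",
                 idx[which(ncol < 3L)[1]]), call. = FALSE)
  }
  get_col <- function(j, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= j) f[j] else default,
           character(1))
  }
  chrom <- get_col(1)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("peak file line %d: non-numeric coordinates", idx[bad[1]]),
         call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("peak file line %d: start >= end", idx[bad[1]]),
         call. = FALSE)
  }
  name <- get_col(4)
  name[is.na(name) | name == "."] <-
    sprintf("peak_%d", which(is.na(name) | name == "."))
  fe <- suppressWarnings(as.numeric(get_col(7)))
  fe[is.na(fe)] <- 0
  summit <- suppressWarnings(as.integer(get_col(10)))
  summit[!is.na(summit) & summit < 0L] <- NA_integer_
  bad <- which(!is.na(summit) & summit >= end - start)
  if (length(bad)) {
    stop(sprintf("peak file line %d: summit offset outside peak",
                 idx[bad[1]]), call. = FALSE)
  }
  peaks(chrom, start, end, name, fe, summit)
}

#' Write peaks as 10-column narrowPeak
#'
#' Round-trips with [read_peaks()]: fold enrichment in column 7, summit
#' offset (or -1) in column 10.
#'
#' @param x A `peaks` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path) {
  stopifnot(inherits(x, "peaks"))
  lines <- paste(x$chrom, x$start, x$end, x$name, 0L, ".",
                 x$fold_enrichment, -1, -1,
                 ifelse(is.na(x$summit), -1L, x$summit),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
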