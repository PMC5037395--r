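# Degenerate IUPAC consensus scanning.

#' Compile an IUPAC consensus pattern
#'
#' Builds per-position allowed-base sets and scanning regexes for a
#' degenerate consensus such as the p53 decamer `RRRCWWGYYY`
#' (Pu-Pu-Pu-C-(A/T)-(T/A)-G-Py-Py-Py).  Pattern `N` matches the four real
#' bases only, never the genome letter `N`.
#'
#' @param pattern Non-empty string over the IUPAC alphabet.
#' @return An `iupac_pattern` list: `pattern`, `length`, `position_sets`,
#'   `revcomp` (the reverse-complement consensus), and internal regexes.
#' @examples
#' p <- compile_iupac("RRRCWWGYYY")
#' p$position_sets[[5]]  # "A" "T"
#' @export
compile_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    stop("pattern must be a non-empty string", call. = FALSE)
  }
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  position_sets <- IUPAC_SETS[chars]
  names(position_sets) <- NULL
  rc <- reverse_complement(pattern)
  structure(list(
    pattern = pattern,
    length = length(chars),
    position_sets = position_sets,
    revcomp = rc,
    regex = iupac_regex(pattern),
    regex_rc = iupac_regex(rc)
  ), class = "iupac_pattern")
}

iupac_regex <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan a sequence for a degenerate consensus
#'
#' Reports every window (overlaps included) whose bases are position-wise
#' members of the pattern's allowed sets.  With `both_strands`, minus-strand
#' matches are found by scanning the reverse-complement pattern and reported
#' at plus-strand coordinates with `strand = "-"`; the `site` column always
#' carries plus-strand letters.  For palindromic consensi (such as
#' `RRRCWWGYYY`, its own reverse complement) the same window can match on
#' both strands; such duplicate (start, site) pairs collapse to a single
#' `+` hit.
#'
#' @param seq Uppercase DNA string.
#' @param pattern An `iupac_pattern` (or a string, compiled on the fly).
#' @param both_strands Scan the minus strand too (default `TRUE`).
#' @param chrom Chromosome label stored in the output (default `""`).
#' @param offset Added to coordinates (for scans of extracted windows).
#' @return A `motif_hits` data frame: `chrom`, `start`, `end`, `strand`,
#'   `site` (0-based half-open, `end - start ==` pattern length).
#' @export
scan_sequence <- function(seq, pattern, both_strands = TRUE, chrom = "",
                          offset = 0L) {
  if (is.character(pattern)) pattern <- compile_iupac(pattern)
  stopifnot(inherits(pattern, "iupac_pattern"), is.character(seq),
            length(seq) == 1L)
  hits <- data.frame(start = regex_starts0(seq, pattern$regex))
  hits$strand <- rep("+", nrow(hits))
  if (both_strands) {
    mstarts <- regex_starts0(seq, pattern$regex_rc)
    if (length(mstarts)) {
      hits <- rbind(hits, data.frame(start = mstarts,
                                     strand = rep("-", length(mstarts))))
    }
  }
  if (!nrow(hits)) return(empty_motif_hits())
  hits$site <- substring(seq, hits$start + 1L, hits$start + pattern$length)
  # Palindromic-consensus collapse: one hit per (start, site), plus wins.
  hits <- hits[order(hits$start, hits$strand != "+"), , drop = FALSE]
  hits <- hits[!duplicated(hits[c("start", "site")]), , drop = FALSE]
  out <- data.frame(chrom = rep(chrom, nrow(hits)),
                    start = as.integer(hits$start + offset),
                    end = as.integer(hits$start + offset + pattern$length),
                    strand = hits$strand,
                    site = hits$site,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

empty_motif_hits <- function() {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    site = character(0), stringsAsFactors = FALSE)
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Scan peak flanks for a consensus motif
#'
#' For each peak, scans the interval `[start - flank, end + flank)` (clamped
#' to chromosome bounds) and reports hits in genomic coordinates, tagged
#' with the peak name.  The per-peak indicator `has_site` summarises whether
#' at least one hit was found.
#'
#' @param x A `peaks` table.
#' @param genome A [genome_sequence].
#' @param pattern An `iupac_pattern` or IUPAC string (default the p53
#'   decamer `RRRCWWGYYY`).
#' @param flank Flank width in bp (default 50, i.e. 50 bp upstream and
#'   downstream of the peak coordinates).
#' @param both_strands Scan both strands (default `TRUE`).
#' @return A list: `hits` (a `motif_hits` data frame with a `peak` column)
#'   and `has_site` (named logical per peak).
#' @export
scan_peak_flanks <- function(x, genome, pattern = "RRRCWWGYYY", flank = 50,
                             both_strands = TRUE) {
  stopifnot(inherits(x, "peaks"), inherits(genome, "genome_sequence"))
  if (is.character(pattern)) pattern <- compile_iupac(pattern)
  all_hits <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    s0 <- max(0L, x$start[i] - as.integer(flank))
    e0 <- min(chrom_length(genome, x$chrom[i]),
              x$end[i] + as.integer(flank))
    win <- get_sequence(genome, x$chrom[i], s0, e0)
    h <- scan_sequence(win, pattern, both_strands = both_strands,
                       chrom = x$chrom[i], offset = s0)
    if (nrow(h)) h$peak <- x$name[i]
    all_hits[[i]] <- h
  }
  keep <- vapply(all_hits, nrow, integer(1)) > 0L
  hits <- if (any(keep)) do.call(rbind, all_hits[keep]) else {
    h <- empty_motif_hits(); h$peak <- character(0); h
  }
  rownames(hits) <- NULL
  class(hits) <- c("motif_hits", "data.frame")
  list(hits = hits,
       has_site = setNames(x$name %in% hits$peak, x$name),
       flank = flank, pattern = pattern$pattern,
       coordinates = "peak boundaries [start - flank, end + flank)")
}

#' Write motif hits as BED6
#'
#' Name column carries the matched site; strand in column 6.
#'
#' @param hits A `motif_hits` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_hits_bed <- function(hits, path) {
  stopifnot(inherits(hits, "motif_hits"))
  lines <- paste(hits$chrom, hits$start, hits$end, hits$site, 0L,
                 hits$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
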