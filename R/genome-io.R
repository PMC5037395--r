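# Genome container and FASTA input.

#' Construct a genome sequence object
#'
#' A genome is represented as a named character vector of uppercase
#' chromosome sequences over the alphabet \{A, C, G, T, N\}.  Sequences are
#' force-uppercased; any other letter is a format error reported with the
#' record name and 1-based offending position.
#'
#' @param sequences Named character vector, one DNA string per chromosome.
#' @return An object of class `genome_sequence`.
#' @examples
#' g <- genome_sequence(c(chr1 = "acgtACGT"))
#' chrom_length(g, "chr1")
#' @export
genome_sequence <- function(sequences) {
  if (!is.character(sequences) || is.null(names(sequences)) ||
      any(!nzchar(names(sequences)))) {
    stop("'sequences' must be a named character vector", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    dup <- unique(names(sequences)[duplicated(names(sequences))])
    stop("duplicate chromosome name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  sequences <- toupper(sequences)
  for (i in seq_along(sequences)) {
    bad <- regexpr("[^ACGTN]", sequences[[i]])
    if (bad != -1L) {
      stop(sprintf(
        "non-DNA character '%s' in record '%s' at position %d",
        substr(sequences[[i]], bad, bad), names(sequences)[i], bad),
        call. = FALSE)
    }
  }
  structure(sequences, class = "genome_sequence")
}

#' Read a genome from a FASTA file
#'
#' All records are loaded and uppercased.  Duplicate headers and non-DNA
#' characters (anything outside A/C/G/T/N after uppercasing) are rejected.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A [genome_sequence] object, records in file order.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop("genome FASTA not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  # FASTA headers may carry descriptions; the chromosome name is word one.
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1L)
  genome_sequence(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_sequence].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_sequence"))
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Chromosome names of a genome
#' @param genome A [genome_sequence].
#' @return Character vector of chromosome names in load order.
#' @export
chrom_names <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  names(genome)
}

#' Chromosome length
#' @param genome A [genome_sequence].
#' @param chrom Chromosome name.
#' @return Length in bp.
#' @export
chrom_length <- function(genome, chrom) {
  nchar(get_chrom(genome, chrom))
}

# Fetch one chromosome string, with a lookup error for unknown names.
get_chrom <- function(genome, chrom) {
  stopifnot(inherits(genome, "genome_sequence"))
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  unclass(genome)[[chrom]]
}

#' Extract genomic subsequence
#'
#' @param genome A [genome_sequence].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval; clamped to chromosome bounds.
#' @return The subsequence as an uppercase string.
#' @export
get_sequence <- function(genome, chrom, start, end) {
  s <- get_chrom(genome, chrom)
  start <- max(0L, as.integer(start))
  end <- min(nchar(s), as.integer(end))
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %d chromosome(s), %s bp total\n",
              length(x), format(sum(nchar(unclass(x))), big.mark = ",")))
  for (nm in head(names(x), 10L)) {
    cat(sprintf("  %-12s %s bp\n", nm,
                format(nchar(unclass(x)[[nm]]), big.mark = ",")))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}
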