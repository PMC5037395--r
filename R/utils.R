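# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Complement map covering the full IUPAC degenerate alphabet.
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", W = "W", S = "S", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

# Allowed-base sets per IUPAC code.  The genome letter N never matches any
# pattern position (including pattern N, which means "any real base").
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA or IUPAC string
#'
#' Complements every character through the IUPAC complement table and reverses
#' the string.  Works on plain DNA and on degenerate consensus strings.
#'
#' @param x Character vector of sequences (uppercase IUPAC letters).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT")        # "ACGT"
#' reverse_complement("RRRCWWGYYY")  # "RRRCWWGYYY" (consensus palindrome)
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    comp <- IUPAC_COMPLEMENT[chars]
    if (anyNA(comp)) {
      stop("reverse_complement(): invalid IUPAC character(s): ",
           paste(unique(chars[is.na(comp)]), collapse = ", "))
    }
    paste(rev(comp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Overlapping match start positions (0-based) of a plain regex in a string.
# Uses a zero-width lookahead so overlapping occurrences are all reported.
regex_starts0 <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

# Random DNA string of length n (uniform base composition).
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Assert a scalar finite number.
check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("'%s' must be a single finite number >= %s", name,
                 format(min)), call. = FALSE)
  }
  invisible(x)
}

# Write a tab-separated report whose single header line starts with '#'.
write_tsv_report <- function(df, path) {
  header <- paste0("#", paste(names(df), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
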