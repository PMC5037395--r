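# Fixture builders and independent brute-force oracles.  The oracles
# re-derive every rule from first principles (their own IUPAC table, their
# own loops) so they share no code with the implementation they check.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp_dna <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

rand_dna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

rand_iupac_pattern <- function(len) {
  paste(sample(names(ORACLE_IUPAC), len, replace = TRUE,
               prob = c(rep(4, 4), rep(2, 6), rep(1, 5))), collapse = "")
}

# Position-wise set-membership scan; minus strand via reverse-complementing
# each window and testing it against the forward pattern.
oracle_scan <- function(seq, pattern, both_strands = TRUE) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  L <- nchar(seq); k <- length(chars)
  hits <- list()
  if (L >= k) {
    for (s in 0:(L - k)) {
      win <- substr(seq, s + 1, s + k)
      wc <- strsplit(win, "", fixed = TRUE)[[1]]
      fwd <- all(mapply(function(b, code) b %in% ORACLE_IUPAC[[code]],
                        wc, chars))
      if (fwd) hits[[length(hits) + 1]] <- list(start = s, strand = "+",
                                                site = win)
      if (both_strands && !any(wc == "N")) {
        rc <- strsplit(oracle_revcomp_dna(win), "", fixed = TRUE)[[1]]
        rev_hit <- all(mapply(function(b, code) b %in% ORACLE_IUPAC[[code]],
                              rc, chars))
        if (rev_hit && !fwd) {
          hits[[length(hits) + 1]] <- list(start = s, strand = "-",
                                           site = win)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), strand = character(0),
                      site = character(0)))
  }
  do.call(rbind, lapply(hits, as.data.frame))
}

# Every (start, unit) candidate tested for maximal whole-unit tiling.
oracle_find_repeats <- function(seq, units = c("TC", "TG"), min_units = 5) {
  L <- nchar(seq)
  out <- list()
  for (u in units) {
    for (s in 0:(L - 2)) {
      if (s >= 2 && substr(seq, s - 1, s) == u) next  # not left-maximal
      k <- 0
      while (s + 2 * (k + 1) <= L &&
             substr(seq, s + 2 * k + 1, s + 2 * k + 2) == u) {
        k <- k + 1
      }
      if (k >= min_units) {
        out[[length(out) + 1]] <- data.frame(start = s, unit = u,
                                             n_units = k)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), unit = character(0),
                      n_units = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$unit), , drop = FALSE]
}

# Exhaustive nearest-downstream-gene assignment over a plain gene table.
oracle_ndg <- function(anchor, chrom, gdf, max_radius) {
  gdf <- gdf[gdf$chrom == chrom, , drop = FALSE]
  tss <- ifelse(gdf$strand == "+", gdf$tx_start, gdf$tx_end - 1)
  d <- ifelse(gdf$strand == "+", anchor - tss, tss - anchor)
  best <- NULL
  for (i in seq_len(nrow(gdf))) {
    if (gdf$tx_start[i] <= anchor && anchor < gdf$tx_end[i]) {
      if (is.null(best) || abs(d[i]) < abs(best$d) ||
          (abs(d[i]) == abs(best$d) && gdf$gene_id[i] < best$gene_id)) {
        best <- list(gene_id = gdf$gene_id[i], d = d[i])
      }
    }
  }
  if (!is.null(best)) return(best)
  for (i in seq_len(nrow(gdf))) {
    upstream <- (gdf$strand[i] == "+" && tss[i] >= anchor) ||
      (gdf$strand[i] == "-" && tss[i] <= anchor)
    if (upstream && abs(d[i]) <= max_radius) {
      if (is.null(best) || abs(d[i]) < abs(best$d) ||
          (abs(d[i]) == abs(best$d) && gdf$gene_id[i] < best$gene_id)) {
        best <- list(gene_id = gdf$gene_id[i], d = d[i])
      }
    }
  }
  if (is.null(best)) list(gene_id = NA_character_, d = NA_integer_) else best
}

# Explicit run-length scan for region calling.
oracle_call_regions <- function(potential, starts, width, cutoff,
                                run_length) {
  ok <- potential >= cutoff
  out <- list()
  i <- 1
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1]) j <- j + 1
      if (j - i + 1 >= run_length) {
        out[[length(out) + 1]] <- data.frame(start = starts[i],
                                             end = starts[j] + width,
                                             n_windows = j - i + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_windows = integer(0)))
  }
  do.call(rbind, out)
}

# A deterministic two-gene fixture used across annotation tests:
# g1 on + covering [10000, 20000), g2 on - covering [30000, 40000).
two_gene_fixture <- function() {
  gene_models(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = c("+", "-"),
    tx_start = c(10000L, 30000L), tx_end = c(20000L, 40000L),
    cds_start = c(10500L, 30500L), cds_end = c(19500L, 39500L),
    exon_starts = list(c(10000L, 12000L, 18000L),
                       c(30000L, 32000L, 38000L)),
    exon_ends = list(c(11000L, 13000L, 20000L),
                     c(31000L, 33000L, 40000L)))
}

small_study <- function(seed = 3, ...) {
  generate_study(synthetic_config(
    seed = seed, n_chroms = 1, chrom_length = 150000, n_genes = 8,
    n_peaks_a = 30, n_peaks_b = 30, ...))
}
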