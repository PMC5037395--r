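# Peak-to-gene annotation: nearest downstream gene, gene components,
# TSS-distance profiling.

COMPONENT_LEVELS <- c("promoter", "five_prime_utr", "first_intron",
                      "cds_exon", "other_intron", "three_prime_utr",
                      "downstream", "intergenic")

# Signed TSS distance of a point in a gene's own orientation:
# negative = upstream of the TSS reading along transcription.
tss_distance_of <- function(anchor, tss, strand) {
  ifelse(strand == "+", anchor - tss, tss - anchor)
}

#' Nearest-downstream-gene assignment for one peak
#'
#' Implements the NDG rule: if the peak anchor lies within any gene body
#' (`tx_start <= anchor < tx_end`) that gene is assigned, choosing the
#' smallest absolute TSS distance on ties; otherwise the assigned gene is the
#' one with the nearest TSS among genes for which the peak is upstream in the
#' gene's own orientation (`+` strand with TSS >= anchor, `-` strand with
#' TSS <= anchor), within `max_radius`.  Remaining ties break to the
#' lexicographically smaller `gene_id` for determinism.
#'
#' @param peak One-row `peaks` table (or any list with `chrom` and `anchor`).
#' @param genes A `gene_models` table.
#' @param max_radius Maximum |TSS distance| for upstream assignment (bp).
#' @return A list with `gene_id` (`NA` if none) and `tss_distance`.
#' @export
nearest_downstream_gene <- function(peak, genes, max_radius = 100000) {
  stopifnot(inherits(genes, "gene_models"))
  assign_gene(peak$chrom[1], peak$anchor[1], genes, max_radius)
}

assign_gene <- function(chrom, anchor, genes, max_radius) {
  if (!chrom %in% genes$chrom) {
    stop("unknown chromosome in gene index: ", chrom, call. = FALSE)
  }
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  d <- tss_distance_of(anchor, g$tss, g$strand)
  inside <- g$tx_start <= anchor & anchor < g$tx_end
  if (any(inside)) {
    cand <- which(inside)
    cand <- cand[order(abs(d[cand]), g$gene_id[cand])]
    i <- cand[1]
    return(list(gene_id = g$gene_id[i], tss_distance = as.integer(d[i])))
  }
  upstream <- ((g$strand == "+" & g$tss >= anchor) |
                 (g$strand == "-" & g$tss <= anchor)) &
    abs(d) <= max_radius
  if (any(upstream)) {
    cand <- which(upstream)
    cand <- cand[order(abs(d[cand]), g$gene_id[cand])]
    i <- cand[1]
    return(list(gene_id = g$gene_id[i], tss_distance = as.integer(d[i])))
  }
  list(gene_id = NA_character_, tss_distance = NA_integer_)
}

# Exon/intron lookup in transcription order for one gene-model row.
# Returns list(kind = "exon"|"intron"|NA, index = transcription-order index).
exon_intron_index <- function(anchor, gene) {
  es <- gene$exon_starts[[1]]; ee <- gene$exon_ends[[1]]
  n <- length(es)
  ex <- which(es <= anchor & anchor < ee)
  if (length(ex)) {
    idx <- if (gene$strand == "+") ex[1] else n + 1L - ex[1]
    return(list(kind = "exon", index = idx))
  }
  if (n >= 2L) {
    intr <- which(ee[-n] <= anchor & anchor < es[-1])
    if (length(intr)) {
      idx <- if (gene$strand == "+") intr[1] else n - intr[1]
      return(list(kind = "intron", index = idx))
    }
  }
  list(kind = NA_character_, index = NA_integer_)
}

#' Classify the gene component at a point
#'
#' Assigns exactly one label per anchor with the fixed precedence
#' promoter > 5'UTR > first intron > CDS exon > other intron > 3'UTR >
#' downstream > intergenic.  "First intron" is the first intron in
#' transcription order (strand-aware).  Exons of non-coding gene models
#' (no CDS) are labelled `cds_exon`, i.e. generic gene-body exon.
#'
#' @param anchor 0-based position on the gene's chromosome.
#' @param gene One-row `gene_models` table.
#' @param promoter_window Promoter extent upstream of the TSS (bp).
#' @param downstream_window Extent past the transcript end (bp).
#' @return One of `promoter`, `five_prime_utr`, `first_intron`, `cds_exon`,
#'   `other_intron`, `three_prime_utr`, `downstream`, `intergenic`.
#' @export
classify_component <- function(anchor, gene, promoter_window = 1000,
                               downstream_window = 1000) {
  stopifnot(inherits(gene, "gene_models"), nrow(gene) == 1L)
  d <- tss_distance_of(anchor, gene$tss, gene$strand)
  if (d >= -promoter_window && d < 0) return("promoter")
  if (gene$tx_start <= anchor && anchor < gene$tx_end) {
    loc <- exon_intron_index(anchor, gene)
    coding <- !is.na(gene$cds_start)
    if (identical(loc$kind, "exon")) {
      if (coding) {
        before_cds <- if (gene$strand == "+") anchor < gene$cds_start
                      else anchor >= gene$cds_end
        after_cds <- if (gene$strand == "+") anchor >= gene$cds_end
                     else anchor < gene$cds_start
        if (before_cds) return("five_prime_utr")
        if (after_cds) return("three_prime_utr")
      }
      return("cds_exon")
    }
    if (identical(loc$kind, "intron")) {
      return(if (loc$index == 1L) "first_intron" else "other_intron")
    }
  }
  in_downstream <- if (gene$strand == "+") {
    anchor >= gene$tx_end && anchor < gene$tx_end + downstream_window
  } else {
    anchor < gene$tx_start && anchor >= gene$tx_start - downstream_window
  }
  if (in_downstream) return("downstream")
  "intergenic"
}

#' Annotate peaks against gene models
#'
#' For each peak anchor: assign a gene by the nearest-downstream-gene rule
#' ([nearest_downstream_gene()]); classify the component at the anchor
#' relative to the assigned gene.  Peaks with no NDG assignment are checked
#' against the downstream windows of all genes (nearest transcript end wins)
#' before falling back to `intergenic` with no gene.
#'
#' @param x A `peaks` table.
#' @param genes A `gene_models` table.
#' @param promoter_window,downstream_window See [classify_component()].
#' @param max_radius See [nearest_downstream_gene()].
#' @return A `peak_annotation` data frame: peak columns plus `gene_id`,
#'   `tss_distance`, `component`.
#' @export
annotate_peaks <- function(x, genes, promoter_window = 1000,
                           downstream_window = 1000, max_radius = 100000) {
  stopifnot(inherits(x, "peaks"), inherits(genes, "gene_models"))
  n <- nrow(x)
  gene_id <- character(n); tssd <- integer(n); comp <- character(n)
  for (i in seq_len(n)) {
    a <- assign_gene(x$chrom[i], x$anchor[i], genes, max_radius)
    if (!is.na(a$gene_id)) {
      gi <- which(genes$gene_id == a$gene_id)[1]
      gene_id[i] <- a$gene_id
      tssd[i] <- a$tss_distance
      comp[i] <- classify_component(x$anchor[i], genes[gi, , drop = FALSE],
                                    promoter_window, downstream_window)
    } else {
      ds <- downstream_fallback(x$chrom[i], x$anchor[i], genes,
                                downstream_window)
      if (!is.na(ds$gene_id)) {
        gene_id[i] <- ds$gene_id
        tssd[i] <- ds$tss_distance
        comp[i] <- "downstream"
      } else {
        gene_id[i] <- NA_character_
        tssd[i] <- NA_integer_
        comp[i] <- "intergenic"
      }
    }
  }
  out <- as.data.frame(x)
  out$gene_id <- gene_id
  out$tss_distance <- tssd
  out$component <- factor(comp, levels = COMPONENT_LEVELS)
  class(out) <- c("peak_annotation", "data.frame")
  out
}

downstream_fallback <- function(chrom, anchor, genes, downstream_window) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  past <- ifelse(g$strand == "+", anchor - g$tx_end, g$tx_start - 1L - anchor)
  hit <- which(past >= 0 & past < downstream_window)
  if (!length(hit)) {
    return(list(gene_id = NA_character_, tss_distance = NA_integer_))
  }
  hit <- hit[order(past[hit], g$gene_id[hit])]
  i <- hit[1]
  list(gene_id = g$gene_id[i],
       tss_distance = as.integer(tss_distance_of(anchor, g$tss[i],
                                                 g$strand[i])))
}

#' Component distribution of annotated peaks
#'
#' Fractions over all peaks (each peak carries exactly one label, so the
#' fractions partition 1).  Also reports the two aggregates used for
#' genome-wide summaries: `regulatory` = promoter + 5'UTR + first intron,
#' and `gene_body` = CDS exon + other intron + 3'UTR.
#'
#' @param annotations A `peak_annotation` table.
#' @return A list with `fractions` (named over all component labels),
#'   `regulatory`, `gene_body`, and `n`.
#' @export
component_distribution <- function(annotations) {
  stopifnot(inherits(annotations, "peak_annotation"))
  n <- nrow(annotations)
  if (n == 0L) stop("empty annotation table", call. = FALSE)
  counts <- table(annotations$component)
  fractions <- as.numeric(counts) / n
  names(fractions) <- names(counts)
  list(
    fractions = fractions,
    regulatory = sum(fractions[c("promoter", "five_prime_utr",
                                 "first_intron")]),
    gene_body = sum(fractions[c("cds_exon", "other_intron",
                                "three_prime_utr")]),
    n = n
  )
}

#' TSS-distance profile in the +/-5 kb window
#'
#' Bins signed TSS distances into ten 1-kb bins spanning -5000..+5000 bp
#' (half-open: a distance d lands in bin `floor((d + 5000)/1000)` when
#' `-5000 <= d < 5000`; d = +5000 is excluded).  Fractions are over all
#' annotated peaks, so they sum to at most 1.  Genes with at least one peak
#' in `[-5000, 0)` form the downstream-target-gene set.
#'
#' @param annotations A `peak_annotation` table.
#' @return A `tss_profile` list: `bin_edges` (11 values), `bin_fractions`
#'   (10 values), `bin_counts`, `downstream_target_genes`, `n`.
#' @export
tss_profile <- function(annotations) {
  stopifnot(inherits(annotations, "peak_annotation"))
  n <- nrow(annotations)
  d <- annotations$tss_distance
  in_window <- !is.na(d) & d >= -5000 & d < 5000
  bin <- floor((d[in_window] + 5000) / 1000)
  counts <- tabulate(bin + 1L, nbins = 10L)
  dtg <- !is.na(d) & d >= -5000 & d < 0 & !is.na(annotations$gene_id)
  structure(list(
    bin_edges = seq(-5000L, 5000L, by = 1000L),
    bin_fractions = counts / n,
    bin_counts = counts,
    downstream_target_genes = sort(unique(annotations$gene_id[dtg])),
    n = n
  ), class = "tss_profile")
}

#' Write a peak-annotation table as TSV
#'
#' Columns: chrom, start, end, name, gene_id, tss_distance, component, one
#' `#`-prefixed header line.
#'
#' @param annotations A `peak_annotation` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotations, path) {
  stopifnot(inherits(annotations, "peak_annotation"))
  df <- annotations[, c("chrom", "start", "end", "name", "gene_id",
                        "tss_distance", "component")]
  df$component <- as.character(df$component)
  write_tsv_report(df, path)
}
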