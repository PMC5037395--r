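# Synthetic study generator: a small genome with gene models, two
# condition-specific peak sets, planted repeats / consensus sites /
# component placement / target overlap, and an exact truth table.

#' Configuration for a synthetic ChIP-seq study
#'
#' The defaults emulate the genome-wide summaries the pipeline is built to
#' recover: 29% of peaks in regulatory components (promoter, 5'UTR, first
#' intron), 53% in the gene body, a 30% rate of a planted p53 decamer within
#' +/-50 bp of the peak, and a configurable overlap between the two
#' conditions' target-gene sets.
#'
#' @param seed Integer; fully determines the study.
#' @param n_chroms,chrom_length Genome shape (uniform base composition).
#' @param n_genes Number of non-overlapping gene models (three exons, coding,
#'   placed with wide intergenic gaps on both strands).
#' @param n_peaks_a,n_peaks_b Peaks per condition (each >= the target-set
#'   size).
#' @param peak_width Peak width in bp.
#' @param frac_regulatory Fraction of peaks planted in promoter / 5'UTR /
#'   first intron (split by `regulatory_split`).
#' @param frac_gene_body Fraction planted in CDS exon / other intron (split
#'   by `gene_body_split`); the remainder is placed intergenically near a
#'   target gene.
#' @param regulatory_split,gene_body_split Relative weights within the two
#'   aggregates.
#' @param frac_p53_flank Fraction of peaks given a planted `RRRCWWGYYY`
#'   instance within `p53_flank` bp of the peak.
#' @param p53_flank Flank used for planting (default 50 bp).
#' @param frac_repeat_peaks Fraction of peaks given a planted (TC)k or (TG)k
#'   run inside the peak.
#' @param repeat_units Units to plant (default `c("TC", "TG")`).
#' @param repeat_length_weights Named numeric vector: sampling weights for
#'   the number of units k (names are k values; default geometric over
#'   5..12).
#' @param target_overlap Fraction of the per-condition target-set size
#'   shared between conditions A and B (planted exactly, as
#'   `round(target_overlap * n_targets)` genes).
#' @param frac_targets Per-condition target-set size as a fraction of
#'   `n_genes` (default 0.5; the shared and unique parts must fit in
#'   `n_genes`).
#' @param promoter_window Promoter extent used when planting promoter peaks.
#' @param min_units Repeat-detection threshold the truth is exact for: the
#'   background is scrubbed of spontaneous runs that could reach it.
#' @param max_retries Rejection-sampling cap per planted feature.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 400000L,
                             n_genes = 40L, n_peaks_a = 300L,
                             n_peaks_b = 300L, peak_width = 200L,
                             frac_regulatory = 0.29, frac_gene_body = 0.53,
                             regulatory_split = c(promoter = 1,
                                                  five_prime_utr = 1,
                                                  first_intron = 1),
                             gene_body_split = c(cds_exon = 1,
                                                 other_intron = 1),
                             frac_p53_flank = 0.3, p53_flank = 50L,
                             frac_repeat_peaks = 0.3,
                             repeat_units = c("TC", "TG"),
                             repeat_length_weights =
                               setNames(0.65^(0:7), 5:12),
                             target_overlap = 0.3, frac_targets = 0.5,
                             promoter_window = 1000L, min_units = 5L,
                             max_retries = 1000L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              n_peaks_a = as.integer(n_peaks_a),
              n_peaks_b = as.integer(n_peaks_b),
              peak_width = as.integer(peak_width),
              frac_regulatory = frac_regulatory,
              frac_gene_body = frac_gene_body,
              regulatory_split = regulatory_split,
              gene_body_split = gene_body_split,
              frac_p53_flank = frac_p53_flank,
              p53_flank = as.integer(p53_flank),
              frac_repeat_peaks = frac_repeat_peaks,
              repeat_units = toupper(repeat_units),
              repeat_length_weights = repeat_length_weights,
              target_overlap = target_overlap,
              frac_targets = frac_targets,
              promoter_window = as.integer(promoter_window),
              min_units = as.integer(min_units),
              max_retries = as.integer(max_retries))
  fr <- c(cfg$frac_regulatory, cfg$frac_gene_body, cfg$frac_p53_flank,
          cfg$frac_repeat_peaks, cfg$target_overlap, cfg$frac_targets)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]",
                                 call. = FALSE)
  if (cfg$frac_regulatory + cfg$frac_gene_body > 1) {
    stop("frac_regulatory + frac_gene_body must be <= 1", call. = FALSE)
  }
  n_t <- max(1L, round(cfg$frac_targets * cfg$n_genes))
  k <- round(cfg$target_overlap * n_t)
  if (n_t - k > cfg$n_genes - n_t) {
    stop("target sets do not fit: need n_targets - n_common <= ",
         "n_genes - n_targets", call. = FALSE)
  }
  if (cfg$n_peaks_a < n_t || cfg$n_peaks_b < n_t) {
    stop("each condition needs at least as many peaks as target genes",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# Break spontaneous repeat runs of >= threshold units (the configured units
# and their complements) by mutating one base per run, iterating until none
# remain.  Keeps the planted truth exact for detection at min_units.
scrub_repeat_runs <- function(seq, units, threshold) {
  all_units <- unique(c(units, reverse_complement(units)))
  repeat {
    found <- FALSE
    for (u in all_units) {
      m <- gregexpr(sprintf("(?:%s){%d,}", u, threshold), seq,
                    perl = TRUE)[[1]]
      if (m[1] == -1L) next
      found <- TRUE
      chars <- strsplit(u, "", fixed = TRUE)[[1]]
      repl_pool <- setdiff(DNA_BASES, chars)
      for (j in seq_along(m)) {
        mid <- as.integer(m[j]) + as.integer(attr(m, "match.length")[j]) %/% 2L
        substr(seq, mid, mid) <- sample(repl_pool, 1L)
      }
    }
    if (!found) return(seq)
  }
}

# Place three-exon coding gene models along the chromosomes with gaps wide
# enough that every planted anchor resolves unambiguously.
place_genes <- function(cfg) {
  gap_min <- max(6000L, 2L * (cfg$promoter_window + 1900L) + 200L)
  margin <- gap_min
  rows <- list()
  struct <- list()
  chrom <- 1L
  cursor <- margin
  for (i in seq_len(cfg$n_genes)) {
    u5 <- sample(150:300, 1); c1 <- sample(150:300, 1)
    i1 <- sample(700:1500, 1); e2 <- sample(150:300, 1)
    i2 <- sample(700:1500, 1); c3 <- sample(150:300, 1)
    u3 <- sample(150:300, 1)
    tx_len <- u5 + c1 + i1 + e2 + i2 + c3 + u3
    while (cursor + tx_len + margin > cfg$chrom_length) {
      chrom <- chrom + 1L
      if (chrom > cfg$n_chroms) {
        stop(sprintf(
          "cannot place %d genes: genome too small (placed %d)",
          cfg$n_genes, i - 1L), call. = FALSE)
      }
      cursor <- margin
    }
    strand <- sample(c("+", "-"), 1)
    g0 <- as.integer(cursor)
    # transcription-order exon intervals (offsets from the TSS)
    t_ex <- rbind(c(0L, u5 + c1),
                  c(u5 + c1 + i1, u5 + c1 + i1 + e2),
                  c(u5 + c1 + i1 + e2 + i2, tx_len))
    if (strand == "+") {
      es <- g0 + t_ex[, 1]; ee <- g0 + t_ex[, 2]
      cs <- g0 + u5; ce <- g0 + tx_len - u3
    } else {
      tx_end <- g0 + tx_len
      es <- rev(tx_end - t_ex[, 2]); ee <- rev(tx_end - t_ex[, 1])
      cs <- g0 + u3; ce <- tx_end - u5
    }
    gid <- sprintf("gene_%03d", i)
    rows[[i]] <- gene_models(
      gene_id = gid, chrom = sprintf("chr%d", chrom), strand = strand,
      tx_start = g0, tx_end = g0 + tx_len,
      cds_start = cs, cds_end = ce,
      exon_starts = list(es), exon_ends = list(ee))
    struct[[i]] <- data.frame(gene_id = gid, u5 = u5, e1 = u5 + c1, i1 = i1,
                              e2 = e2, i2 = i2, tx_len = tx_len)
    cursor <- as.integer(cursor + tx_len + sample(gap_min:(gap_min + 3000L), 1))
  }
  genes <- do.call(rbind, rows)
  class(genes) <- c("gene_models", "data.frame")
  rownames(genes) <- NULL
  list(genes = genes, struct = do.call(rbind, struct), gap_min = gap_min)
}

# Transcription-offset t (may be negative = upstream) to genomic position.
genomic_from_t <- function(gene, t) {
  if (gene$strand == "+") gene$tx_start + t else gene$tx_end - 1L - t
}

# Draw an anchor (genomic) realizing a planted component for a gene.
draw_anchor <- function(component, gene, st, cfg) {
  t <- switch(component,
    promoter = -sample(seq_len(cfg$promoter_window), 1),
    five_prime_utr = sample(0:(st$u5 - 1L), 1),
    first_intron = st$e1 + sample(0:(st$i1 - 1L), 1),
    cds_exon = st$e1 + st$i1 + sample(0:(st$e2 - 1L), 1),
    other_intron = st$e1 + st$i1 + st$e2 + sample(0:(st$i2 - 1L), 1),
    # past the promoter window but nearer than any other gene's TSS, so the
    # NDG assignment still resolves to this gene with label "intergenic"
    intergenic = -(cfg$promoter_window + sample(401:1900, 1)),
    stop("unknown planted component: ", component)
  )
  list(t = t, anchor = as.integer(genomic_from_t(gene, t)))
}

#' Generate a synthetic study
#'
#' Builds a uniform-composition genome, places gene models, plants two
#' condition-specific peak sets realizing the configured component
#' fractions and target-set overlap, and writes repeat runs and p53
#' consensus instances into the genome at recorded coordinates.  Planted
#' features never overlap each other; spontaneous background runs of the
#' repeat units are scrubbed below the detection threshold first, so the
#' truth table is exact for repeat detection.  The same seed reproduces the
#' study byte for byte.
#'
#' @param cfg A [synthetic_config()].
#' @return A `synthetic_study` list: `genome`, `genes`, `peaks_a`,
#'   `peaks_b`, `truth` (one row per peak), `targets_a`, `targets_b`,
#'   `planted_common`, `config`.
#' @export
generate_study <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))

  seqs <- setNames(vapply(chroms, function(ch) random_dna(cfg$chrom_length),
                          character(1)), chroms)
  seqs <- vapply(seqs, scrub_repeat_runs, character(1),
                 units = cfg$repeat_units,
                 threshold = max(2L, cfg$min_units - 1L))

  placed <- place_genes(cfg)
  genes <- placed$genes
  struct <- placed$struct

  # planted target sets with exact overlap
  n_t <- max(1L, round(cfg$frac_targets * cfg$n_genes))
  k_common <- round(cfg$target_overlap * n_t)
  targets_a <- sort(sample(genes$gene_id, n_t))
  shared <- sort(sample(targets_a, k_common))
  targets_b <- sort(c(shared, sample(setdiff(genes$gene_id, targets_a),
                                     n_t - k_common)))

  occupied <- lapply(setNames(nm = chroms),
                     function(ch) logical(cfg$chrom_length))
  reserve <- function(ch, s, e) {
    idx <- (s + 1L):e
    if (s < 0L || e > cfg$chrom_length || any(occupied[[ch]][idx])) {
      return(FALSE)
    }
    occupied[[ch]][idx] <<- TRUE
    TRUE
  }
  write_seq <- function(ch, pos0, text) {
    substr(seqs[[ch]], pos0 + 1L, pos0 + nchar(text)) <<- text
  }

  comp_names <- c("promoter", "five_prime_utr", "first_intron",
                  "cds_exon", "other_intron", "intergenic")
  rs <- cfg$regulatory_split / sum(cfg$regulatory_split)
  gs <- cfg$gene_body_split / sum(cfg$gene_body_split)
  comp_probs <- c(cfg$frac_regulatory * rs, cfg$frac_gene_body * gs,
                  1 - cfg$frac_regulatory - cfg$frac_gene_body)
  p53_pat <- compile_iupac("RRRCWWGYYY")
  k_vals <- as.integer(names(cfg$repeat_length_weights))

  make_condition <- function(cond, n_peaks, targets) {
    gene_pool <- sample(c(targets,
                          sample(targets, n_peaks - length(targets),
                                 replace = TRUE)))
    components <- sample(comp_names, n_peaks, replace = TRUE,
                         prob = comp_probs)
    has_repeat <- seq_len(n_peaks) %in%
      sample(n_peaks, round(cfg$frac_repeat_peaks * n_peaks))
    has_p53 <- seq_len(n_peaks) %in%
      sample(n_peaks, round(cfg$frac_p53_flank * n_peaks))
    half <- cfg$peak_width %/% 2L

    rows <- vector("list", n_peaks)
    for (i in seq_len(n_peaks)) {
      gid <- gene_pool[i]
      gi <- which(genes$gene_id == gid)
      gene <- genes[gi, , drop = FALSE]
      st <- struct[struct$gene_id == gid, , drop = FALSE]
      da <- draw_anchor(components[i], gene, st, cfg)
      jitter <- sample(-30:30, 1)
      start <- da$anchor - half + jitter
      end <- start + cfg$peak_width
      name <- sprintf("%s_peak_%04d", cond, i)
      row <- list(condition = cond, name = name, chrom = gene$chrom,
                  start = start, end = end,
                  summit = da$anchor - start,
                  fold_enrichment = round(2 + stats::rexp(1, 0.15), 2),
                  gene_id = gid, component = components[i],
                  tss_distance = da$t,
                  repeat_unit = NA_character_,
                  repeat_n_units = NA_integer_,
                  repeat_start = NA_integer_,
                  p53_start = NA_integer_, p53_site = NA_character_)

      if (has_repeat[i]) {
        unit <- sample(cfg$repeat_units, 1)
        k <- sample(k_vals, 1, prob = cfg$repeat_length_weights)
        len <- 2L * k
        ok <- FALSE
        for (try in seq_len(cfg$max_retries)) {
          pos <- sample(seq.int(start + 1L, end - len - 1L), 1)
          if (reserve(gene$chrom, pos - 1L, pos + len + 1L)) { ok <- TRUE; break }
        }
        if (!ok) stop(sprintf(
          "could not place repeat for %s after %d retries", name,
          cfg$max_retries), call. = FALSE)
        uc <- strsplit(unit, "", fixed = TRUE)[[1]]
        guard <- function(avoid) if (avoid == "A") "G" else "A"
        write_seq(gene$chrom, pos - 1L, guard(uc[2]))
        write_seq(gene$chrom, pos, strrep(unit, k))
        write_seq(gene$chrom, pos + len, guard(uc[1]))
        row$repeat_unit <- unit; row$repeat_n_units <- k
        row$repeat_start <- pos
      }

      if (has_p53[i]) {
        site <- paste(vapply(p53_pat$position_sets,
                             function(s) sample(s, 1), character(1)),
                      collapse = "")
        ok <- FALSE
        for (try in seq_len(cfg$max_retries)) {
          pos <- sample(seq.int(start - cfg$p53_flank,
                                end + cfg$p53_flank - 10L), 1)
          if (reserve(gene$chrom, pos, pos + 10L)) { ok <- TRUE; break }
        }
        if (!ok) stop(sprintf(
          "could not place p53 site for %s after %d retries", name,
          cfg$max_retries), call. = FALSE)
        write_seq(gene$chrom, pos, site)
        row$p53_start <- pos; row$p53_site <- site
      }
      rows[[i]] <- row
    }
    do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                stringsAsFactors = FALSE)))
  }

  truth_a <- make_condition("a", cfg$n_peaks_a, targets_a)
  truth_b <- make_condition("b", cfg$n_peaks_b, targets_b)
  truth <- rbind(truth_a, truth_b)
  rownames(truth) <- NULL

  to_peaks <- function(tr) {
    peaks(tr$chrom, tr$start, tr$end, tr$name, tr$fold_enrichment, tr$summit)
  }
  structure(list(
    genome = genome_sequence(seqs),
    genes = genes,
    peaks_a = to_peaks(truth_a),
    peaks_b = to_peaks(truth_b),
    truth = truth,
    targets_a = targets_a,
    targets_b = targets_b,
    planted_common = length(shared),
    config = cfg
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_study> %d chrom(s) x %s bp, %d genes, ",
    "%d + %d peaks, %d common target genes planted\n"),
    x$config$n_chroms, format(x$config$chrom_length, big.mark = ","),
    nrow(x$genes), nrow(x$peaks_a), nrow(x$peaks_b), x$planted_common))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits `genome.fa`, `genes.bed` (BED12), `peaks_a.narrowPeak`,
#' `peaks_b.narrowPeak` and `truth.tsv` into `dir`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(study$genome, file.path(dir, "genome.fa"))
  write_gene_models_bed12(study$genes, file.path(dir, "genes.bed"))
  write_peaks(study$peaks_a, file.path(dir, "peaks_a.narrowPeak"))
  write_peaks(study$peaks_b, file.path(dir, "peaks_b.narrowPeak"))
  write_tsv_report(study$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Run the full pipeline on a synthetic study
#'
#' Fold-filters, annotates and profiles both peak sets, scans peak flanks
#' for the p53 consensus, detects repeat runs inside peaks, and compares
#' the two conditions' target-gene sets.
#'
#' @param study A `synthetic_study`.
#' @param min_fold Fold-enrichment filter applied before annotation.
#' @param promoter_window,downstream_window,max_radius Annotation settings.
#' @param pattern,flank Consensus scan settings.
#' @param units,min_units Repeat detection settings (default from the study
#'   config).
#' @return A list: `annotations`, `tss_profiles`, `flank_scan`, `repeats`
#'   (each with members `a` and `b`), and `comparison`.
#' @export
run_study_pipeline <- function(study, min_fold = 2,
                               promoter_window = 1000,
                               downstream_window = 1000,
                               max_radius = 100000,
                               pattern = "RRRCWWGYYY", flank = 50,
                               units = NULL, min_units = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  units <- units %||% study$config$repeat_units
  min_units <- min_units %||% study$config$min_units
  one <- function(pk) {
    pk <- filter_peaks_by_fold(pk, min_fold)
    ann <- annotate_peaks(pk, study$genes, promoter_window,
                          downstream_window, max_radius)
    scan <- scan_peak_flanks(pk, study$genome, pattern, flank)
    reps <- lapply(seq_len(nrow(pk)), function(i) {
      r <- find_repeats(get_sequence(study$genome, pk$chrom[i], pk$start[i],
                                     pk$end[i]),
                        units = units, min_units = min_units,
                        chrom = pk$chrom[i], offset = pk$start[i])
      if (nrow(r)) r$peak <- pk$name[i]
      r
    })
    reps <- do.call(rbind, reps[vapply(reps, nrow, integer(1)) > 0L])
    list(peaks = pk, annotation = ann, profile = tss_profile(ann),
         flank_scan = scan, repeats = reps)
  }
  a <- one(study$peaks_a); b <- one(study$peaks_b)
  list(
    annotations = list(a = a$annotation, b = b$annotation),
    tss_profiles = list(a = a$profile, b = b$profile),
    flank_scan = list(a = a$flank_scan, b = b$flank_scan),
    repeats = list(a = a$repeats, b = b$repeats),
    comparison = compare_targets(target_genes(a$annotation),
                                 target_genes(b$annotation))
  )
}

#' Score pipeline outputs against the planted truth
#'
#' Computes, per condition: absolute deviation of the estimated regulatory
#' and gene-body fractions from the configured ones; per-peak component and
#' gene agreement; recall (and precision against the study-wide truth) for
#' planted p53 sites and repeat runs; and the realized versus planted
#' target-overlap decomposition.  p53 precision counts background consensus
#' matches (which are left in the genome by design) as false positives.
#'
#' @param study A `synthetic_study`.
#' @param results Output of [run_study_pipeline()] (run with defaults when
#'   omitted).
#' @return A `recovery_report` list.
#' @export
evaluate_recovery <- function(study, results = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  if (is.null(results)) results <- run_study_pipeline(study)
  cfg <- study$config
  report <- list()
  for (cond in c("a", "b")) {
    tr <- study$truth[study$truth$condition == cond, , drop = FALSE]
    ann <- results$annotations[[cond]]
    m <- match(tr$name, ann$name)
    dist <- component_distribution(ann)
    comp_ok <- as.character(ann$component[m]) == tr$component
    gene_ok <- ann$gene_id[m] == tr$gene_id
    # p53 recall: the planted decamer of each peak found in its own flanks
    hits <- results$flank_scan[[cond]]$hits
    planted <- tr[!is.na(tr$p53_start), , drop = FALSE]
    p53_found <- vapply(seq_len(nrow(planted)), function(j) {
      any(hits$peak == planted$name[j] & hits$start == planted$p53_start[j])
    }, logical(1))
    p53_precision <- if (nrow(hits)) {
      truth_sites <- study$truth$p53_start[!is.na(study$truth$p53_start)]
      mean(hits$start %in% truth_sites)
    } else NA_real_
    # repeats: recall per planted run, precision vs study-wide truth
    reps <- results$repeats[[cond]]
    rt <- tr[!is.na(tr$repeat_start), , drop = FALSE]
    rep_found <- vapply(seq_len(nrow(rt)), function(j) {
      any(reps$peak == rt$name[j] & reps$start == rt$repeat_start[j] &
            reps$unit == rt$repeat_unit[j] &
            reps$n_units == rt$repeat_n_units[j])
    }, logical(1))
    # precision: a detected run is true when it overlaps a planted run of
    # the same unit anywhere in the study (peak windows overlap, so a run
    # planted for one peak may be seen, possibly clipped, from another)
    all_rt <- study$truth[!is.na(study$truth$repeat_start), , drop = FALSE]
    rep_precision <- if (!is.null(reps) && nrow(reps)) {
      mean(vapply(seq_len(nrow(reps)), function(j) {
        any(all_rt$repeat_unit == reps$unit[j] &
              all_rt$repeat_start < reps$end[j] &
              all_rt$repeat_start + 2L * all_rt$repeat_n_units >
                reps$start[j])
      }, logical(1)))
    } else NA_real_
    report[[cond]] <- list(
      regulatory_fraction = dist$regulatory,
      gene_body_fraction = dist$gene_body,
      regulatory_deviation = abs(dist$regulatory - cfg$frac_regulatory),
      gene_body_deviation = abs(dist$gene_body - cfg$frac_gene_body),
      component_accuracy = mean(comp_ok),
      gene_accuracy = mean(gene_ok),
      p53_recall = if (nrow(planted)) mean(p53_found) else NA_real_,
      p53_precision = p53_precision,
      repeat_recall = if (nrow(rt)) mean(rep_found) else NA_real_,
      repeat_precision = rep_precision
    )
  }
  planted_counts <- c(common = study$planted_common,
                      unique_a = length(study$targets_a) -
                        study$planted_common,
                      unique_b = length(study$targets_b) -
                        study$planted_common)
  structure(list(
    a = report$a, b = report$b,
    planted_counts = planted_counts,
    realized_counts = results$comparison$counts,
    overlap_exact = all(results$comparison$counts == planted_counts)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  for (cond in c("a", "b")) {
    r <- x[[cond]]
    cat(sprintf(paste0(
      "  condition %s: regulatory %.3f (dev %.3f), gene body %.3f ",
      "(dev %.3f), component acc %.3f, p53 recall %s, repeat recall %s\n"),
      cond, r$regulatory_fraction, r$regulatory_deviation,
      r$gene_body_fraction, r$gene_body_deviation, r$component_accuracy,
      format(r$p53_recall), format(r$repeat_recall)))
  }
  cat(sprintf("  target overlap planted (%s) realized (%s): %s\n",
              paste(x$planted_counts, collapse = ", "),
              paste(x$realized_counts, collapse = ", "),
              if (x$overlap_exact) "exact" else "MISMATCH"))
  invisible(x)
}
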