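# IUPAC consensus scanning and dinucleotide repeat detection.

test_that("IUPAC compilation builds position sets and rejects bad codes", {
  p <- compile_iupac("RRRCWWGYYY")
  expect_equal(p$length, 10L)
  expect_equal(p$position_sets[[5]], c("A", "T"))
  expect_equal(p$position_sets[[4]], "C")
  # the p53 consensus is its own reverse complement
  expect_equal(p$revcomp, p$pattern)
  q <- compile_iupac("ACGT")
  expect_true(all(lengths(q$position_sets) == 1L))
  expect_error(compile_iupac("ACGZ"), "Z")
  expect_error(compile_iupac(""), "non-empty")
})

test_that("consensus scanning handles the worked decamer cases", {
  hits <- scan_sequence("AGACATGTCT", "RRRCWWGYYY")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$strand, "+")  # palindromic duplicate collapsed
  expect_equal(hits$site, "AGACATGTCT")
  expect_equal(nrow(scan_sequence("TTTTTTTTTT", "RRRCWWGYYY")), 0L)
  # genome N never matches, not even pattern N
  expect_equal(nrow(scan_sequence("AGNCATGTCT", "RRNCWWGYYY")), 0L)
})

test_that("scanning agrees with the position-wise membership oracle", {
  set.seed(512)
  for (i in 1:300) {
    seq <- rand_dna(sample(20:60, 1))
    pat <- rand_iupac_pattern(sample(4:8, 1))
    got <- scan_sequence(seq, pat)
    want <- oracle_scan(seq, pat)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, as.character(want$strand))
      expect_equal(got$site, as.character(want$site))
    }
  }
})

test_that("reverse-complement scanning mirrors coordinates", {
  set.seed(513)
  for (i in 1:50) {
    seq <- rand_dna(60)
    pat <- rand_iupac_pattern(5)
    fwd <- scan_sequence(seq, pat)
    rc <- scan_sequence(oracle_revcomp_dna(seq), pat)
    # a hit at s in the mirrored sequence corresponds to 60 - 5 - s here
    expect_setequal(fwd$start, 60 - 5 - rc$start)
  }
})

test_that("flank scanning respects the +/-50 bp window and clamps", {
  site <- "AGACATGTCT"
  left <- rand_dna(60)
  g <- genome_sequence(c(chr1 = paste0(substr(left, 1, 60), site,
                                       rand_dna(130))))
  # site occupies [60, 70); peak [100, 120): 60 >= 100 - 50 -> reported
  pk <- peaks("chr1", 100, 120, "p1")
  res <- scan_peak_flanks(pk, g)
  expect_true(res$has_site[["p1"]])
  expect_true(any(res$hits$start == 60 & res$hits$peak == "p1"))
  # peak [121, 141): window starts at 71 > 60 -> not reported
  pk2 <- peaks("chr1", 121, 141, "p2")
  expect_false(scan_peak_flanks(pk2, g)$has_site[["p2"]])
  # clamping at the chromosome start must not error
  pk3 <- peaks("chr1", 5, 30, "p3")
  expect_no_error(scan_peak_flanks(pk3, g))
  expect_error(scan_peak_flanks(peaks("chrX", 0, 10), g),
               "unknown chromosome")
})

test_that("repeat detection handles the oligo cases exactly", {
  r <- find_repeats(strrep("TC", 10))
  expect_equal(nrow(r), 1L)
  expect_equal(r$unit, "TC")
  expect_equal(r$n_units, 10L)
  expect_equal(r$length, 20L)
  expect_equal(nrow(find_repeats("AAAA")), 0L)
  # trailing half unit is not counted
  r2 <- find_repeats(paste0("AA", strrep("TG", 6), "T", "AA"), min_units = 5)
  expect_equal(r2$n_units, 6L)
  expect_equal(r2$start, 2L)
  expect_error(find_repeats("ACGT", min_units = 1), "min_units")
})

test_that("repeat detection agrees with the exhaustive tiling oracle", {
  set.seed(600)
  for (i in 1:400) {
    # T/C/G-heavy alphabet so runs arise spontaneously, plus planted runs
    seq <- rand_dna(120, prob = c(0.1, 0.35, 0.2, 0.35))
    if (i %% 3 == 0) {
      u <- sample(c("TC", "TG"), 1)
      k <- sample(3:8, 1)
      pos <- sample(1:(120 - 2 * k), 1)
      substr(seq, pos, pos + 2 * k - 1) <- strrep(u, k)
    }
    got <- find_repeats(seq, min_units = 3)
    want <- oracle_find_repeats(seq, min_units = 3)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$unit, as.character(want$unit))
      expect_equal(got$n_units, want$n_units)
    }
  }
})

test_that("runs are maximal, non-overlapping per unit, and monotone in
           min_units", {
  set.seed(601)
  for (i in 1:50) {
    seq <- rand_dna(300, prob = c(0.1, 0.35, 0.2, 0.35))
    runs <- find_repeats(seq, min_units = 2)
    for (u in c("TC", "TG")) {
      ru <- runs[runs$unit == u, , drop = FALSE]
      if (nrow(ru) > 1) {
        expect_true(all(ru$start[-1] >= ru$end[-nrow(ru)]))
      }
      for (j in seq_len(nrow(ru))) {
        expect_false(substr(seq, ru$start[j] - 1, ru$start[j]) == u)
        expect_false(substr(seq, ru$end[j] + 1, ru$end[j] + 2) == u)
      }
    }
    n2 <- nrow(runs)
    n3 <- nrow(find_repeats(seq, min_units = 3))
    n5 <- nrow(find_repeats(seq, min_units = 5))
    expect_true(n2 >= n3 && n3 >= n5)
  }
})

test_that("complementary-strand units report the plus-strand unit", {
  seq <- paste0("AAA", strrep("GA", 6), "TTT")  # (TC)6 on the minus strand
  r <- find_repeats(seq, min_units = 5, both_strands = TRUE)
  expect_equal(nrow(r), 1L)
  expect_equal(r$unit, "TC")
  expect_equal(r$strand, "-")
  expect_equal(r$start, 3L)
})

test_that("repeat histograms partition the run list", {
  runs <- find_repeats(paste0(strrep("TC", 5), "AAA", strrep("TC", 5),
                              "GGG", strrep("TC", 7), "A", strrep("TG", 6)))
  h <- repeat_distribution(runs)
  expect_equal(h$count[h$unit == "TC" & h$n_units == 5], 2L)
  expect_equal(h$count[h$unit == "TC" & h$n_units == 7], 1L)
  expect_equal(sum(h$count), nrow(runs))
  expect_equal(attr(h, "totals")[["TC"]], 3L)
  empty <- repeat_distribution(find_repeats("ACGT"))
  expect_equal(nrow(empty), 0L)
})

test_that("planted repeat length distribution is recovered exactly", {
  st <- small_study(seed = 33, frac_repeat_peaks = 0.6)
  res <- run_study_pipeline(st)
  truth <- st$truth[!is.na(st$truth$repeat_start), ]
  detected <- rbind(res$repeats$a, res$repeats$b)
  # every planted (start, unit, n_units) triple appears among detections
  expect_true(all(paste(truth$repeat_start, truth$repeat_unit,
                        truth$repeat_n_units) %in%
                    paste(detected$start, detected$unit,
                          detected$n_units)))
})

test_that("shuffle enrichment is deterministic and calibrated", {
  set.seed(88)
  g <- genome_sequence(c(chr1 = rand_dna(20000)))
  pk <- peaks("chr1", (0:39) * 500L, (0:39) * 500L + 400L)
  e1 <- repeat_enrichment(pk, g, min_units = 2, n_shuffles = 19, seed = 9)
  e2 <- repeat_enrichment(pk, g, min_units = 2, n_shuffles = 19, seed = 9)
  expect_identical(e1, e2)
  expect_true(e1$empirical_p > 0 && e1$empirical_p <= 1)
  expect_error(repeat_enrichment(pk[0, ], g), "empty")
})
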