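# Sliding-window MAR potential scoring and region calling.

test_that("window arithmetic follows the truncation rule", {
  cfg <- mar_config()
  expect_equal(nrow(sliding_windows(2000, cfg)), 11L)
  w <- sliding_windows(2000, cfg)
  expect_equal(w$start[11], 1000)
  expect_equal(w$end[11], 2000)
  expect_equal(nrow(sliding_windows(1000, cfg)), 1L)
  expect_equal(nrow(sliding_windows(1050, cfg)), 1L)  # remainder discarded
  expect_error(sliding_windows(999, cfg), "shorter")
  expect_error(mar_config(window_width = 50, slide = 100), "slide")
  expect_error(mar_config(cutoff = 1.5), "cutoff")
})

test_that("rule scores saturate and respect composition bounds", {
  at <- mar_rule("at_richness", type = "at_content")
  expect_equal(rule_score(strrep("AT", 500), at), 1)
  expect_equal(rule_score(strrep("GC", 500), at), 0)
  expect_equal(rule_score(paste0(strrep("AT", 310), strrep("GC", 190)), at),
               (0.62 - 0.5) / 0.25)
  # planted copies: score = count / saturation until it clamps at 1
  r <- mar_rule("ori_signal", patterns = "ATTTA", saturation_count = 4)
  mk <- function(n) {
    paste0(paste(rep("ATTTA", n), collapse = strrep("G", 10)),
           strrep("G", 1000))
  }
  expect_equal(rule_score(substr(mk(3), 1, 1000), r), 3 / 4)
  expect_equal(rule_score(substr(mk(4), 1, 1000), r), 1)
  expect_equal(rule_score(substr(mk(5), 1, 1000), r), 1)  # clamped
  # pattern with A/T content scores 0 on pure GC
  expect_equal(rule_score(strrep("GC", 500), r), 0)
})

test_that("gapped and degenerate patterns count both strands with overlap", {
  r <- mar_rule("kinked_dna", patterns = "TAX{3}TG", saturation_count = 2)
  win <- paste0("TACCCTG", strrep("G", 93))
  expect_equal(rule_score(win, r), 0.5)  # one fwd hit (+ no revcomp hit)
  # a self-complementary context counts on both strands
  r2 <- mar_rule("pal", patterns = "ACGT", saturation_count = 4)
  expect_equal(rule_score(paste0("ACGT", strrep("G", 96)), r2), 0.5)
})

test_that("potential is the weighted mean of rule scores", {
  r1 <- mar_rule("always", patterns = "A", weight = 1, saturation_count = 1)
  r2 <- mar_rule("never", patterns = "AAAAAAAAAA", weight = 3,
                 saturation_count = 1)
  cfg <- mar_config(window_width = 100, slide = 100)
  # window of alternating AG: rule 1 saturates (hits >= 1), rule 2 zero
  prof <- mar_profile(strrep("AG", 100), list(r1, r2), cfg)
  expect_equal(prof$potential, rep(0.25, 2))  # (1*1 + 3*0) / 4
  # degenerate single-rule case: potential equals the rule score vector
  prof1 <- mar_profile(strrep("AG", 100), list(r2), cfg)
  expect_equal(prof1$potential, rep(0, 2))
  expect_error(mar_profile(strrep("A", 200), list(), cfg), "empty")
  # hand-computed weighted mean with scores (1.0, 0.5), weights (1, 3)
  expect_equal((1 * 1 + 3 * 0.5) / 4, 0.625)
  wa <- mar_rule("w1", patterns = "CCCC", weight = 1, saturation_count = 1)
  wb <- mar_rule("w2", patterns = "CCCCCCCC", weight = 3,
                 saturation_count = 2)
  win <- paste0(strrep("C", 8), strrep("A", 92))  # w1 saturates, w2 = 0.5
  prof2 <- mar_profile(win, list(wa, wb),
                       mar_config(window_width = 100, slide = 100))
  expect_equal(prof2$potential, 0.625)
})

test_that("potential stays in [0, 1] and the profile is deterministic", {
  set.seed(71)
  seq <- rand_dna(3000, prob = c(0.3, 0.2, 0.2, 0.3))
  prof <- mar_profile(seq)
  expect_true(all(prof$potential >= 0 & prof$potential <= 1))
  expect_identical(prof, mar_profile(seq))
})

test_that("region calling matches the spelled-out run rules", {
  cfg <- mar_config()
  p <- peakscape:::mar_profile_from_potential(c(0.7, 0.7, 0.7), cfg)
  r <- call_mar_regions(p)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 0)
  expect_equal(r$end, 200 + 1000)  # three windows at slide 100
  expect_equal(r$n_windows, 3L)
  # a sub-cutoff gap splits runs; max qualifying run of 2 -> nothing called
  p2 <- peakscape:::mar_profile_from_potential(c(0.7, 0.5, 0.7, 0.7), cfg)
  expect_equal(nrow(call_mar_regions(p2)), 0L)
  # two runs separated by one low window stay two regions
  p3 <- peakscape:::mar_profile_from_potential(
    c(0.9, 0.9, 0.9, 0.1, 0.9, 0.9, 0.9), cfg)
  expect_equal(nrow(call_mar_regions(p3)), 2L)
})

test_that("region calling agrees with a brute-force run scanner", {
  set.seed(72)
  cfg <- mar_config()
  for (i in 1:200) {
    pot <- round(runif(sample(3:30, 1)), 2)
    prof <- peakscape:::mar_profile_from_potential(pot, cfg)
    got <- call_mar_regions(prof)
    want <- oracle_call_regions(pot, prof$window_starts, cfg$window_width,
                                cfg$cutoff, cfg$run_length)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_windows, want$n_windows)
    }
  }
})

test_that("MAR rules round-trip through YAML", {
  rules <- default_mar_rules()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_mar_rules(rules, f)
  back <- read_mar_rules(f)
  expect_equal(lapply(back, unclass), lapply(rules, unclass))
})

test_that("a planted MAR-like island produces a called region", {
  set.seed(73)
  # 1.65 kb AT-rich core seeded with instances of every pattern family:
  # ori ATTA/ATTTA, curved TTTAAA, TG-richness TGTTTTG, kinked TA-NNN-TG-
  # NNN-CA, topo-II GTNWAYATTNATNNR, plus high A+T content
  unit <- paste0("ATTTA", "TTTAAA", "TGTTTTG", "TAGGGTGCCCCA",
                 "GTAAACATTAATGCA", "ATTAATTTAT")
  core <- paste(rep(unit, 30), collapse = "")
  seq <- paste0(rand_dna(2000), core, rand_dna(2000))
  prof <- mar_profile(seq)
  regions <- call_mar_regions(prof)
  expect_gte(nrow(regions), 1L)
  expect_true(any(regions$start < 2000 + nchar(core) & regions$end > 2000))
})
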