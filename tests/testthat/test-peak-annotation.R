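# Nearest-downstream-gene assignment, component classification, TSS profile.

test_that("NDG assignment matches the worked upstream/containment cases", {
  genes <- two_gene_fixture()
  pk <- function(anchor) peaks("chr1", anchor - 50L, anchor + 50L)
  # upstream of a + gene: negative distance in gene orientation
  a <- nearest_downstream_gene(pk(9300), genes)
  expect_equal(a$gene_id, "g1")
  expect_equal(a$tss_distance, -700L)
  # upstream of a - gene (TSS at 39999) lies to its right
  a <- nearest_downstream_gene(pk(40600), genes)
  expect_equal(a$gene_id, "g2")
  expect_equal(a$tss_distance, -601L)
  # containment beats distance
  a <- nearest_downstream_gene(pk(15000), genes)
  expect_equal(a$gene_id, "g1")
  expect_equal(a$tss_distance, 5000L)
  # beyond max_radius: no assignment
  a <- nearest_downstream_gene(pk(9300), genes, max_radius = 500)
  expect_true(is.na(a$gene_id))
  expect_error(nearest_downstream_gene(peaks("chrX", 0, 10), genes),
               "unknown chromosome")
})

test_that("NDG agrees with exhaustive search over random gene sets", {
  set.seed(202)
  for (rep in 1:20) {
    n_genes <- sample(5:50, 1)
    s <- sort(sample.int(500000, n_genes)) * 2L
    len <- sample(500:5000, n_genes, replace = TRUE)
    gdf <- data.frame(gene_id = sprintf("g%02d", sample(n_genes)),
                      chrom = "chr1",
                      strand = sample(c("+", "-"), n_genes, TRUE),
                      tx_start = s, tx_end = s + len)
    gm <- gene_models(gdf$gene_id, gdf$chrom, gdf$strand, gdf$tx_start,
                      gdf$tx_end)
    for (k in 1:50) {
      anchor <- sample.int(1100000, 1)
      got <- peakscape:::assign_gene("chr1", anchor, gm, 100000)
      want <- oracle_ndg(anchor, "chr1", gdf, 100000)
      expect_identical(got$gene_id, want$gene_id)
      if (!is.na(want$gene_id)) {
        expect_equal(got$tss_distance, as.integer(want$d))
      }
    }
  }
})

test_that("component labels follow the worked precedence cases", {
  genes <- two_gene_fixture()
  g1 <- genes[1, , drop = FALSE]
  g2 <- genes[2, , drop = FALSE]
  expect_equal(classify_component(9300, g1), "promoter")
  expect_equal(classify_component(10200, g1), "five_prime_utr")
  expect_equal(classify_component(11500, g1), "first_intron")  # 1st intron
  expect_equal(classify_component(12500, g1), "cds_exon")
  expect_equal(classify_component(15000, g1), "other_intron")
  expect_equal(classify_component(19700, g1), "three_prime_utr")
  expect_equal(classify_component(20500, g1), "downstream")
  expect_equal(classify_component(25000, g1), "intergenic")
  # strand-aware mirror on the - gene: first intron is the rightmost one
  expect_equal(classify_component(39700, g2), "five_prime_utr")
  expect_equal(classify_component(39300, g2), "cds_exon")
  expect_equal(classify_component(37000, g2), "first_intron")
  expect_equal(classify_component(31500, g2), "other_intron")
  expect_equal(classify_component(30200, g2), "three_prime_utr")
  expect_equal(classify_component(29700, g2), "downstream")
  expect_equal(classify_component(40200, g2), "promoter")
})

test_that("moving an anchor against transcription decreases tss_distance", {
  genes <- two_gene_fixture()
  g1 <- genes[1, , drop = FALSE]; g2 <- genes[2, , drop = FALSE]
  d_plus <- sapply(c(9000, 9500, 10000, 15000),
                   function(a) peakscape:::tss_distance_of(a, g1$tss,
                                                           g1$strand))
  expect_true(all(diff(d_plus) > 0))
  d_minus <- sapply(c(41000, 40500, 39999, 35000),
                    function(a) peakscape:::tss_distance_of(a, g2$tss,
                                                            g2$strand))
  expect_true(all(diff(d_minus) > 0))
})

test_that("every peak gets exactly one component and fractions sum to 1", {
  st <- small_study(seed = 21)
  ann <- annotate_peaks(st$peaks_a, st$genes)
  expect_false(anyNA(ann$component))
  dist <- component_distribution(ann)
  expect_equal(sum(dist$fractions), 1, tolerance = 1e-9)
  expect_equal(dist$regulatory,
               sum(dist$fractions[c("promoter", "five_prime_utr",
                                    "first_intron")]))
  empty <- ann[0, , drop = FALSE]
  class(empty) <- class(ann)
  expect_error(component_distribution(empty), "empty")
})

test_that("component counting matches a hand-built annotation", {
  ann <- data.frame(
    gene_id = c("a", "a", "b", NA),
    tss_distance = c(-700L, -100L, 2000L, NA),
    component = factor(c("promoter", "promoter", "cds_exon", "intergenic"),
                       levels = peakscape:::COMPONENT_LEVELS))
  class(ann) <- c("peak_annotation", "data.frame")
  dist <- component_distribution(ann)
  expect_equal(unname(dist$fractions[c("promoter", "cds_exon",
                                       "intergenic")]),
               c(0.5, 0.25, 0.25))
  expect_equal(dist$regulatory, 0.5)
  expect_equal(dist$gene_body, 0.25)
})

test_that("TSS profile bins are half-open 1-kb bins over +/-5 kb", {
  mk <- function(d, gid = "g") {
    ann <- data.frame(gene_id = gid, tss_distance = as.integer(d),
                      component = factor("promoter",
                                         peakscape:::COMPONENT_LEVELS))
    class(ann) <- c("peak_annotation", "data.frame")
    ann
  }
  pr <- tss_profile(mk(-700))
  expect_equal(pr$bin_fractions[5], 1)  # bin [-1000, 0)
  expect_equal(sum(pr$bin_fractions), 1)
  # boundary conventions: -5000 counted in the first bin, +5000 excluded
  expect_equal(tss_profile(mk(-5000))$bin_fractions[1], 1)
  expect_equal(sum(tss_profile(mk(5000))$bin_fractions), 0)
  # downstream target genes: at least one peak in [-5000, 0)
  expect_equal(tss_profile(mk(-700))$downstream_target_genes, "g")
  expect_equal(length(tss_profile(mk(300))$downstream_target_genes), 0L)
})

test_that("a planted promoter excess makes [-1000, 0) the modal bin", {
  st <- generate_study(synthetic_config(
    seed = 8, n_chroms = 1, chrom_length = 150000, n_genes = 8,
    n_peaks_a = 200, n_peaks_b = 8,
    frac_regulatory = 0.4,
    regulatory_split = c(promoter = 1, five_prime_utr = 0,
                         first_intron = 0)))
  pr <- tss_profile(annotate_peaks(st$peaks_a, st$genes))
  expect_equal(which.max(pr$bin_fractions), 5L)  # [-1000, 0)
  expect_gt(pr$bin_fractions[5], 0.3)
})
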