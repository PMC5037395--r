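# peakscape

Interpreting ChIP-seq peak calls for matrix-attachment-region binding
proteins (MARBPs) and transcription factors, at desk scale and fully
offline.

Peak callers tell you *where* a protein binds; the biological questions come
after: which gene does each peak act on, in which gene component does it sit,
how does the target repertoire shift between two cellular conditions (for
example p53-proficient versus p53-null cells), does a sequence motif or
microsatellite repeat underlie the binding, and does the bound region look
like a scaffold/matrix attachment region (S/MAR)?  `peakscape` implements
this downstream layer as a small set of composable, deterministic functions,
plus a synthetic-study generator that plants every feature with a truth
table so the whole pipeline is testable without any genome download.

## What it computes

* **Nearest-downstream-gene (NDG) annotation.**  Each peak is reduced to a
  single-bp anchor (summit if available, midpoint otherwise).  An anchor
  inside a gene body is assigned to that gene; otherwise it is assigned to
  the nearest gene transcribed away from it (strand `+` with TSS ≥ anchor,
  strand `−` with TSS ≤ anchor) within a search radius.  The signed TSS
  distance *d* is measured in the gene's own orientation (*d* < 0 =
  upstream), and each peak receives exactly one component label with fixed
  precedence: promoter > 5′UTR > first intron > CDS exon > other intron >
  3′UTR > downstream > intergenic.
* **TSS-distance profile.**  Peak fractions in ten 1-kb bins over
  −5 kb ≤ *d* < +5 kb; genes with a peak at −5 kb ≤ *d* < 0 form the
  downstream-target-gene set.
* **Two-condition target comparison.**  Fold-enrichment filtering, then the
  common / unique-A / unique-B decomposition of the two conditions' distinct
  target-gene sets.
* **Degenerate consensus scanning.**  IUPAC patterns such as the p53
  response-element decamer 5′-Pu Pu Pu C (A/T) (T/A) G Py Py Py-3′
  (`RRRCWWGYYY`) are scanned over both strands in peak flanks
  (`[start − 50, end + 50)` by default), with palindromic duplicates
  collapsed.
* **Dinucleotide repeat runs.**  Maximal perfect tilings of 2-mer units
  (default the T(C/G) family, `TC`/`TG`) with ≥ *k* whole units, plus a
  length/frequency histogram and an empirical enrichment test against
  per-sequence base-composition-preserving shuffles.
* **MAR potential.**  Rule-based sliding-window scoring (window 1000 bp,
  slide 100 bp): six rule families (ORI signals, TG-richness, curved and
  kinked DNA, topoisomerase II consensus, AT-richness), each scoring
  `min(1, hits / saturation)` on both strands, combined as a weighted mean
  into a potential in [0, 1]; regions are called where ≥ 3 consecutive
  windows reach the 0.60 cutoff.  All patterns, weights and thresholds are
  overridable via a YAML rules file.
* **Relative quantification.**  `fold = 2^−ΔΔCt` with
  `ΔΔCt = ΔCt(control) − ΔCt(treatment)` and
  `ΔCt = Ct(target) − Ct(reference)`; the opposite (Livak) sign convention
  is available via `convention = "standard"`.

## Worked example

```r
library(peakscape)

study <- generate_study(synthetic_config(seed = 17))
study
#> <synthetic_study> 2 chrom(s) x 400,000 bp, 40 genes, 300 + 300 peaks,
#>   6 common target genes planted

ann  <- annotate_peaks(study$peaks_a, study$genes)
dist <- component_distribution(ann)
round(dist$fractions, 3)
#>        promoter  five_prime_utr    first_intron        cds_exon
#>           0.080           0.120           0.093           0.267
#>    other_intron three_prime_utr      downstream      intergenic
#>           0.240           0.000           0.000           0.200
c(regulatory = dist$regulatory, gene_body = dist$gene_body)
#> regulatory: 0.293   gene body: 0.507
```

The study was configured to place 29% of peaks in regulatory components
(promoter, 5′UTR, first intron) and 53% in the gene body; at n = 300 peaks
the pipeline recovers 29.3% and 50.7% — binomial sampling noise, not
annotation error (per-peak component accuracy on the truth table is 100%).

```r
ann_b <- annotate_peaks(study$peaks_b, study$genes)
compare_targets(target_genes(ann), target_genes(ann_b))
#> <target_comparison> common: 6, unique A: 14, unique B: 14

scan <- scan_peak_flanks(study$peaks_a, study$genome, "RRRCWWGYYY",
                         flank = 50)
sum(scan$has_site)
#> [1] 161   # 30% planted + palindromic consensus background
```

The planted common-target count (6) is recovered exactly — target-set
recovery is a set identity, not an estimate.

A command-line wrapper for shell pipelines is installed at
`system.file("scripts", "peakscape.R", package = "peakscape")` with
subcommands `annotate`, `compare`, `scan-motif`, `find-repeats`, `mar`,
`ddct`, and `simulate`.

## Scope

`peakscape` consumes peak calls and annotations; read QC, alignment and
peak calling (and de novo motif discovery, GO enrichment, genome-browser
visualisation) are upstream/downstream of it and out of scope.  See the
methods vignette (`vignettes/peakscape-methods.Rmd`) for the model
assumptions, parameter choices, and what the synthetic studies do and do
not establish about real data.
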