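---
title: "peakscape: methods, parameter choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peakscape: methods, parameter choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakscape)
```

This vignette is the package's account of its own science: the models and
procedures it implements, the parameters that matter and why their defaults
are what they are, the places where the design was genuinely open and what
was chosen, and what the passing test suite does and does not establish.

## Coordinates and domain objects

All coordinates are 0-based, half-open (the BED convention); 1-based
coordinates appear only inside the GTF dialect, converted on input.  A
genome is a named set of uppercase chromosome strings over {A, C, G, T, N};
N is a legal genome letter but never matches any pattern position, including
pattern `N`, which means "any real base" — conservative masking.  A gene
model is a transcript span with strand, sorted non-overlapping exons, and
optional CDS bounds; its TSS is `tx_start` on `+` and `tx_end − 1` on `−`.
A peak is an interval with an optional summit offset and a fold-enrichment
score; every downstream step uses its single-bp *anchor* — the summit when
the caller reported one, else the midpoint.  The summit is the best
single-bp proxy for the binding site; the midpoint is the deterministic
fallback, so a peak file without summits is still fully usable.

## Peak-to-gene assignment and gene components

The nearest-downstream-gene (NDG) rule assigns an anchor inside any gene
body to that gene (smallest |TSS distance| on ties); otherwise to the gene
with the nearest TSS among genes transcribed away from the peak (strand `+`
with TSS ≥ anchor, `−` with TSS ≤ anchor) within `max_radius` (default
100 kb — generous enough for promoter-proximal biology, configurable
because no universal value exists).  Remaining ties break to the
lexicographically smaller gene id, purely for determinism.  TSS distances
are signed in the gene's own orientation, so "upstream" means the same
thing on both strands.

Each peak receives exactly one component label with fixed precedence
promoter > 5′UTR > first intron > CDS exon > other intron > 3′UTR >
downstream > intergenic.  Consequences of the single-label design: the
component fractions partition 1 exactly, which is what makes the summary
distribution interpretable as a composition.  "First intron" is the first
intron in transcription order, i.e. the genomically *last* intron of a `−`
gene — the biological reading of 5′ regulatory intron.  Exons of non-coding
models (no CDS) are labelled `cds_exon` in the sense of generic gene-body
exon; a finer non-coding vocabulary was judged not worth a ninth label.
The promoter window defaults to 1000 bp because the −1..0 kb TSS bin is the
natural operational definition of the proximal promoter at this resolution;
the downstream window defaults to the same 1000 bp for symmetry.  Both are
arguments, not constants.

The TSS profile bins signed distances into ten 1-kb half-open bins over
[−5000, 5000); d = −5000 is counted, d = +5000 is not.  Because peak-level
fractions and gene-level target sets answer different questions (a gene
with five promoter peaks is one target but five binned peaks), the profile
reports both: `bin_fractions` are per-peak, `downstream_target_genes`
(genes with ≥ 1 peak at −5 kb ≤ d < 0) is per-gene, and they are never
mixed.

## Target-set comparison

A condition's target set is the set of distinct assigned gene ids over its
annotated peaks — duplicates collapse, because targets are genes, not
peaks.  The common/unique decomposition is exact set algebra after
whitespace-stripping, case-sensitive matching.  Fold-enrichment filtering
(`fold_enrichment ≥ min_fold`, order-preserving) defaults to 2.0; upstream
pipelines filter on fold enrichment but rarely publish the cutoff, so it is
a visible, configurable parameter rather than a hidden constant.

## Consensus scanning

IUPAC patterns compile to per-position allowed-base sets.  Scanning reports
every window (overlaps included) that matches position-wise; minus-strand
hits are found by scanning the reverse-complement pattern and reported at
plus-strand coordinates, with the site always in plus-strand letters.  The
p53 decamer `RRRCWWGYYY` is its own reverse complement at the consensus
level, so every forward hit would duplicate as a minus hit; duplicate
(start, site) pairs collapse to a single `+` hit to avoid double counting.
Flank scanning searches `[start − flank, end + flank)` with `flank = 50`
by default, clamped at chromosome ends; whether peak boundaries or summits
anchor the ±50 bp window is genuinely ambiguous in common usage, so the
choice (boundaries) is recorded in the scan's output metadata.  Both
strands are scanned by default — nearly moot for a palindromic consensus,
but not for user-supplied patterns.

## Repeat runs and the enrichment null

A repeat run is a *maximal perfect tiling* of a 2-mer unit counted in whole
units: no mismatches, trailing odd bases excluded, runs of different units
never merged.  Perfection keeps the definition oracle-testable (the test
suite checks equivalence against an exhaustive per-(start, unit) scanner)
and matches the pure competition-oligo design — (TC)~10~ / (TG)~10~ — that
motivates the T(C/G) default unit set.  `min_units` defaults to 5
(10 bp), the shortest run on the length scale of a 10-bp response element;
it is configurable and the run count is monotonically non-increasing in it.
With `both_strands`, the complementary units (GA, CA) are searched and
reported under the plus-strand unit they represent.

The enrichment statistic is run density (runs per kbp) in peak sequences
versus per-sequence shuffled controls, with the add-one empirical p-value
`(1 + #{null ≥ obs}) / (1 + n_shuffles)`.  The null preserves each
sequence's *base* composition.  A stricter null that also preserved
dinucleotide composition was considered and rejected on logical grounds:
for a sequence that *is* a dinucleotide repeat, dinucleotide-preserving
shuffles reproduce the sequence (a pure (TC)~k~ tract tiles into identical
TC tiles, and its overlapping-dinucleotide graph forces the same
alternation), so the null equals the observation and the test has zero
power against exactly the alternative it exists for.  Base-composition
preservation still controls the first-order confounder (T/C-rich sequences
trivially contain more TC) while leaving ordering free.  With a fixed seed
the result is bit-reproducible; `n_shuffles ≥ 19` is required for p < 0.05
to be attainable, and 99 is the default.

## MAR potential

Rule-based S/MAR prediction scores each sliding window (default width
1000 bp, slide 100 bp) under six classic rule families: origin-of-
replication signals (ATTA/ATTTA/ATTTTA), TG-richness, curved DNA
(phased A/T tracts and TTTAAA), kinked DNA (TA/TG/CA triplets at fixed
3-bp gaps), the vertebrate topoisomerase-II consensus, and window AT
content.  Pattern rules score `min(1, hits / saturation_count)` with hits
counted on both strands, overlaps allowed — MARs are strand-agnostic
structural elements, and saturation keeps every score in [0, 1] so the
combined potential is as well.  The AT rule maps AT fraction affinely from
0.5 → 0 to 0.75 → 1.  The per-window potential is the *weighted mean* of
rule scores.  A product combiner was the plausible alternative; the mean
was chosen because it degrades gracefully (one absent rule family does not
zero the potential) and is declared in the profile's `combiner` field so
the choice is visible in output.  The shipped pattern strings follow the
canonical rule families of the rule-based MAR-finder literature, but the
engine is deliberately independent of them: all patterns, weights and
saturation counts load from a YAML rules file, and the test suite
exercises the engine with planted custom patterns rather than trusting any
default set.

Region calling takes maximal runs of ≥ `run_length` consecutive windows
with potential ≥ `cutoff` (defaults 3 and 0.60, the classic slider
settings, also the published ones for this pipeline's use case) and spans
them from first window start to last window end.  Two qualifying runs
separated by a single sub-cutoff window remain two regions.

## Relative quantification

`ddct_fold_change()` evaluates `2^−ΔΔCt` with
`ΔΔCt = ΔCt(control) − ΔCt(treatment)`, `ΔCt = Ct(target) − Ct(reference)`
— implemented verbatim in that sign convention, although the more common
Livak convention negates it, because the two differ by exact reciprocal and
silently "fixing" a stated convention is worse than exposing both.  The
`convention` argument (`"as-printed"` / `"standard"`) is the escape hatch.
Inputs must be finite positive cycle numbers; reciprocal symmetry
(swap control and treatment ⇒ reciprocal fold) holds to machine precision
and is tested at 1000 random quadruples.

## The synthetic-study generator

`generate_study()` builds: a uniform-composition genome (default 2 ×
400 kb); non-overlapping three-exon coding gene models on both strands
with wide intergenic gaps; and two condition-specific peak sets whose
placement realizes configured component fractions — default 29%
regulatory, 53% gene body, the remainder intergenic-but-assignable — by a
per-peak multinomial draw recorded in the truth table.  Planted features:

* a (TC)~k~ or (TG)~k~ run inside a configurable fraction of peaks
  (default 0.3), k drawn from a geometric-weight histogram over 5..12 —
  a realistic microsatellite length range;
* a concrete `RRRCWWGYYY` instance, each degenerate position sampled
  uniformly from its allowed set (so the full IUPAC matcher is exercised),
  within ±50 bp of a configurable fraction of peaks (default 0.3);
* a target-gene overlap between conditions planted *exactly*:
  `round(target_overlap · n_targets)` shared genes, every target covered
  by at least one peak.

Three design points make the truth table exact rather than approximate.
First, gene gaps are sized so that every planted anchor resolves to its
intended gene under the NDG rule with a margin (the worked geometry:
upstream offsets never exceed half the minimum gap minus a margin).
Second, spontaneous background runs of the repeat units (or their
complements) are scrubbed below the detection threshold before planting,
and each planted run gets guard bases so it cannot extend; planted
features are placed through a collision registry with a bounded retry
count (default 1000), after which generation fails loudly rather than
degrading.  Third, p53-consensus background matches are deliberately *not*
scrubbed: a degenerate decamer matches uniform DNA at a predictable rate
(2^8/4^10 per strand per position), and that background is part of what a
scan of real flanks would face, so recall is asserted against planted
sites while precision is reported against the study-wide truth and is
expected below 1.

What the generator does **not** emulate: non-uniform base composition and
isochores, repeat families other than the planted units, overlapping and
nested genes, multi-transcript loci, chromatin-driven peak-width and
fold-enrichment structure, and read-level noise (peaks are consumed
post-calling by construction).  Passing recovery tests therefore
establishes that the *algorithms* are correct and calibrated on their own
assumptions — not that any particular biological dataset would yield any
particular fraction.  Genome-scale percentages from real studies are in
general not desk-reproducible (they depend on raw data and tool versions);
what is reproducible is exact recovery of planted truth, and that is what
the acceptance checks assert.

## Problem sizes and numerical conventions

The shipped tests run at sizes chosen to make binomial tolerances
meaningful while keeping the suite fast: component-fraction recovery at
n = 1000 peaks against a ±0.045 band (≈ 3σ for a 0.29 proportion),
overlap identity across 100 random small configurations, oracle
equivalence at ≥ 1000 random instances per operation, and enrichment
calibration at 200 uniform 1-kb peaks (ratio within [0.8, 1.2]).
Fractions sum to 1 within 1e−9; set identities and oracle equivalences are
exact; reciprocal symmetry is checked at 1e−12.  Degenerate inputs fail
loudly: empty annotation tables, empty rule lists, empty peak sets,
sequences shorter than a window, non-finite Ct values and negative
thresholds are all errors, not silent defaults.

## Known limitations

* One label per peak by anchor point: a broad peak spanning a promoter and
  first exon is counted once, by its anchor.  This is what makes the
  composition sum to 1; interval-overlap multi-labelling is deliberately
  out of scope.
* Each input record is one gene model; collapsing multiple transcripts per
  gene is left to the user upstream, since no collapsing rule is neutral.
* The GTF reader is minimal (exon features, `gene_id` attribute) by
  design; GTF-derived models are non-coding as far as UTR/CDS labels go.
* Repeat runs are perfect tilings; imperfect microsatellites with point
  interruptions count as separate runs.
* The MAR default rule set is a reconstruction of the classic rule
  families, not a reimplementation of any specific closed tool; absolute
  potential values are comparable within a rules file, not across tools.
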