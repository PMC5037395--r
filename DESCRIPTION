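Package: peakscape
Title: ChIP-Seq Peak Annotation, Repeat and Consensus Scanning, and
    MAR-Potential Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for interpreting transcription-factor and
    matrix-attachment-region binding-protein ChIP-seq peak calls. Provides
    gene-component annotation with nearest-downstream-gene assignment and
    TSS-distance profiling, fold-enrichment filtering and two-condition
    target-set comparison, degenerate IUPAC consensus scanning in peak flanks
    (for example the p53 decamer RRRCWWGYYY), dinucleotide microsatellite run
    detection with a shuffle-based enrichment test, rule-based sliding-window
    MAR-potential scoring, and 2^-ddCt relative quantification. Ships a
    synthetic-study generator that plants gene components, repeat runs,
    consensus sites and target-set overlap with a machine-readable truth
    table, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
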