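Package: seesawr
Title: Inverse Differential-Expression ("Seesaw") Analysis for Two-Stress
    Transcriptome Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of paired differential-expression contrasts
    from two-stress designs, built around the detection of inversely
    regulated ("seesaw") genes: quadrant classification of per-gene log2
    fold-change pairs, FDR-thresholded seesaw calling, randomization-based
    gene-set overlap enrichment with a hypergeometric oracle, chromosome-
    scale spatial statistics (per-chromosome bias tests with Yates
    correction, sliding-window enrichment tracks, maximal co-localization
    clustering against randomized gene-order nulls), operon-level
    directional summaries, and expression-library QC (replicate
    correlations, PCA component retention by Kaiser and broken-stick rules,
    FPKM, germline-enrichment classification). Includes a synthetic-data
    generator that plants the statistical structure these analyses assume,
    with a per-gene truth table for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
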