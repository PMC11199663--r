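Package: clonotrace
Title: Clonal Lineage Tracing and Diversity Analytics for Barcoded Cell
    Line Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for genomic barcoding of targeted-integration
    CHO producer cell lines. Covers barcode library design with fixed
    metadata positions, flank-anchored barcode extraction from merged
    amplicon reads, separation of genuine clone barcodes from sequencing
    artifacts by Levenshtein-distance clustering and an unbiased knee-point
    read-count threshold, clonal diversity estimation (Chao1 richness,
    resampling, collision probability, pool trajectories, RMCE efficiency),
    a Poisson limiting-dilution probability-of-clonality model with
    recovery-rate estimation, lineage-aware clone screening (sibling versus
    relative clones, diversity-controlled screening arms, maximum-titer
    screening-depth curves), and a synthetic-data generator that emulates
    the whole cell line development process for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
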