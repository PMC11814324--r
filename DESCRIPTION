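Package: chromage
Title: Histone-Mark Dynamics, Euchromatin Scores and Epigenetic Age
    Acceleration in Cell-Type-Specific Chromatin Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of cell-type-specific histone-modification
    profiling (ChIP-seq / CUT&Tag) quantified as region-by-sample count
    matrices. Implements median-of-ratios normalization, per-gene z-scores
    and the H3K27ac minus H3K27me3 euchromatin score, a negative-binomial
    Wald test for differential enrichment with Benjamini-Hochberg control,
    kmeans chromatin-state clustering with bivalent-cluster selection and
    H2AK119ub high/low splitting, a linear euchromatin-score clock that
    estimates epigenetic age and its acceleration, trajectory-shape
    classification, a polycomb CBX paralog-switch statistic with a
    permutation null, and gene-set overlap and enrichment tests. Ships a
    negative-binomial synthetic-study generator with planted gene classes
    and a known aging-acceleration factor so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    fgsea,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
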