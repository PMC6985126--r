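Package: miproteo
Title: Microscaled Proteogenomic Analysis of TMT Core-Biopsy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for microscaled tandem-mass-tag (TMT)
    proteogenomics of serial tumor core biopsies. Implements PSM-level quality
    filtering and median rollup to common-reference log2 ratios, median/MAD
    sample normalization, upper-quartile RNA normalization, tumor-content and
    TMT labeling QC gates, gene-level copy number and a length-weighted
    chromosome instability index, outlier Z-score analysis against a reference
    distribution built from pathological-complete-response (pCR) baseline
    samples, single-sample gene-set (ssGSEA-style) and PTM-signature
    (PTM-SEA-style) weighted Kolmogorov-Smirnov enrichment, exact Wilcoxon
    signed-rank and rank-sum tests, limma-based moderated-t differential
    analysis with plex batch coefficients, ERBB2-amplicon multi-omic status
    classification, and offline literature-association tallying. Ships a
    seeded synthetic cohort generator emulating the pre/on-treatment TMT
    plex design with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
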