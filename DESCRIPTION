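Package: toxseq
Title: Dose-Series Transcriptomics and Window-Based Chromatin Accessibility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for low-dose toxicogenomics screens on in vitro
    thyroid models: biotype composition quality control with IQR outlier
    flagging, negative-binomial polynomial dose-response testing with profile
    clustering, removal of unwanted variation via factor analysis of control
    genes or replicate sets, relevance-filtered negative-binomial Wald
    differential expression with a spurious single-replicate spike filter,
    preranked gene set enrichment with a weighted running-sum statistic, and
    sliding-window differential chromatin accessibility from ATAC fragment
    files with region merging and region-level false discovery rate control.
    Includes seeded synthetic-data generators that emulate the count and
    fragment structure of such experiments so that every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
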