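Package: fibrosen
Title: Transcriptome Time-Course Analysis of Replicative Senescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of bulk RNA-seq time courses across
    population doublings of aging fibroblast cultures: RPKM
    normalization, sample-structure diagnostics (Spearman correlation
    heat-map ordering and PCA), consensus negative-binomial exact
    differential-expression testing under two dispersion models,
    recurrence accounting of differentially expressed genes across
    ordered comparisons, fuzzy c-means clustering of concatenated
    two-cell-line temporal profiles with automatic selection of the
    cluster number by a validity-index ensemble, monotonic-trend
    classification with replicate resampling and exact small-n Spearman
    null distributions, and cross-platform fold-change concordance
    against qPCR and protein measurements. Includes a seeded synthetic
    count generator with planted ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
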