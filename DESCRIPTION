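Package: mammosig
Title: Cell-of-Origin Signatures and Nearest-Centroid Classification for
    Mammary Cell Subpopulations and Breast Tumours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds cell-type centroids of gene expression for purified normal
    mammary subpopulations from empirical-Bayes moderated-t differential
    expression rankings with Storey q-value FDR control, scores breast tumour
    profiles against those centroids by Pearson correlation and by explicit
    mixture decomposition (partial correlations from multivariate regression),
    and classifies tumours with a two-level nearest-centroid decision tree,
    including intrinsic subtyping from a user-supplied SSP centroid table.
    Also provides single-hit Poisson limiting-dilution analysis of mammary
    repopulating unit (MRU) frequencies with confidence intervals and
    population MRU shares, delta-delta-Ct relative quantification of qPCR
    plates with two-housekeeper normalization, and seeded synthetic-data
    generators that emulate the structure of a sorted-cell expression atlas,
    tumour mixture cohorts, limiting-dilution assays and qPCR plates so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
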