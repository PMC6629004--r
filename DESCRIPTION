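Package: triomics
Title: Integrative CNV-Methylation-Expression Subtyping of Tumor Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-omics molecular subtyping pipeline for tumor cohorts
    profiled for DNA copy number (segmented CNV), DNA methylation (450K-style
    beta values), mRNA expression (FPKM and counts), somatic mutations and
    clinical follow-up. Screens genes whose expression tracks their own copy
    number (CNVcor) or promoter methylation (METcor) via Fisher-z transformed
    Pearson correlations, derives molecular subtypes both by consensus
    non-negative matrix factorization (Brunet KL variant with cophenetic,
    dispersion and silhouette rank selection) and by a sparse Gaussian
    latent-factor integrative clustering of all three layers, quantifies
    per-sample aberration burdens and their cross-correlations, contrasts
    subtypes by exact contingency tests, negative-binomial differential
    expression and mutation spectra, and attaches Kaplan-Meier, log-rank and
    Cox survival statistics. A synthetic-cohort generator with known ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    cluster,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
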