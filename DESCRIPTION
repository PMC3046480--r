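Package: nmadomains
Title: Calling Nuclear-Membrane-Association Domains from Tiling-Array and
    Sequencing ChIP Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies chromosomal subdomains of nuclear-membrane
    association (such as LEM-2 contact regions in C. elegans embryos) from
    ChIP signal on either tiling microarrays or short-read sequencing.
    Provides GC-stratified robust normalization and median smoothing of
    per-probe log-ratios, input-subtracted z-score coverage tracks for
    sequencing data, a binarized sliding-window subdomain caller with
    control-based empirical false-discovery ratio, cross-platform
    validation, gap derivation and size classification, boundary-aligned
    metaprofiles of features and signal, and the associated enrichment
    statistics (repeat-family and gene coverage contrasts, expression by
    gap class, silent-gene fate, phenotype enrichment, occupancy-size
    regression, fusion-chromosome comparison). A synthetic-genome
    simulator plants ground-truth association domains with the arm
    architecture, repeat and gene biases, chromatin marks, and staged
    expression that the analysis assumes, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
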