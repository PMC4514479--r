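Package: chirpmotif
Title: Enrichment-Score Peak Calling and Motif Analysis for Dual-Probe
    RNA Pulldown Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for ChIRP/RAP-style RNA pulldown sequencing
    experiments that use two disjoint antisense probe pools (odd and even)
    against the target RNA plus a LacZ probe-pool control. Computes a
    per-position enrichment score (EScore) as the minimum library-scaled
    coverage across the two pulldown pools normalised to the control track,
    merges scored positions into regions, calls peaks on mean log2 EScore,
    discovers a position weight matrix motif in top peak sequences by
    expectation-maximization, scans transcript sets with exact position
    p-values and per-sequence E-values, and tests motif enrichment in
    differentially expressed transcript classes with a resampling t-test
    design. Includes a synthetic-data generator emulating the full
    experimental design so the pipeline is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
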