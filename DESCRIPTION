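Package: readclouds
Title: Barcode Deconvolution and Evaluation for Synthetic Long-Read
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with synthetic long-read (linked-read)
    metagenomic libraries, where reads sharing a 3' unique molecular
    identifier (UMI) form a "read cloud" that typically mixes several
    genomic fragments.  The package splits read clouds into
    single-fragment "enhanced" read clouds by bounded Dijkstra search
    over a condensed de Bruijn assembly graph, provides a gold-standard
    reference deconvolution from alignment positions, quantifies cloud
    quality (purity, Shannon entropy, under/complete/over
    classification), promotes per-read taxonomic classifications to the
    per-cloud majority consensus, and simulates truth-tracked barcoded
    libraries so the whole stack can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    parallel,
    Rcpp,
    readr,
    rlang,
    Rsamtools,
    S4Vectors,
    stringr,
    tibble,
    withr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
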