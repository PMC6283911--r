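Package: earminer
Title: Identification and Downstream Analysis of EAR Repression Motif Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects EAR (Ethylene-responsive element binding factor-associated
    Amphiphilic Repression) motifs (LxLxL and DLNx[1,2]P) in plant protein
    sequences, expands a seed set of known EAR proteins by an iterated
    profile-HMM search with literal-pattern filtering, and transfers candidates
    across species through reciprocal-best-hit orthology with bootstrap
    support. Also provides the downstream analytics used to annotate EAR
    proteins: promoter cis-element enrichment against a resampled background,
    overlap-based gene set enrichment, differential-expression filtering,
    epigenetic peak-to-gene association, co-expression network construction
    (Pearson correlation and mutual rank) and k-clique-percolation functional
    modules. Includes synthetic-data generators with recorded ground truth so
    every stage can be benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
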