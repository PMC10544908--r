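Package: ribodom
Title: Quantifying Nucleolar Dominance from Barcoded ITS Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for measuring nucleolar dominance in
    interspecific grass hybrids (Festuca x Lolium) from barcoded ITS1/ITS2
    amplicon reads. Merges paired-end reads by best ungapped overlap with a
    quality-aware consensus, demultiplexes on dual 12-bp barcodes, trims
    primers, screens inserts against a parental reference database, and
    dereplicates them into ribotype count tables. Ribotypes are assigned to
    parental types by best-hit identity against species-labelled references,
    with region-specific identity thresholds derived from between-species
    p-distances (pairwise deletion); global singletons are removed. Parental
    proportions are compared between genomic DNA and cDNA templates to
    quantify dominance, and rarefied ribotype diversity is analysed across
    generations with depth-bias diagnostics and one-way ANOVA. A fully
    specified synthetic-data generator with per-read truth manifests lets the
    whole pipeline run and be validated without external data.
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
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
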