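Package: lakeassembly
Title: Community Assembly and Co-Occurrence Analysis for Lake Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical inference for amplicon surveys of lake microbial
    communities: alpha and beta diversity with group tests, environmental
    driver attribution (redundancy analysis, spatial eigenfunctions,
    variation partitioning), quantification of community assembly processes
    (Sloan neutral community model, phylogenetic beta-nearest-taxon-index
    and abundance-based Raup-Crick null models with a five-way process
    classification), and thresholded Spearman co-occurrence networks
    compared against Erdos-Renyi random ensembles. Includes a synthetic
    metacommunity generator with controllable assembly regimes so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    minpack.lm,
    picante,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
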