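Package: plasticmine
Title: Mining Genome Collections for Plastic-Degrading Enzyme Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for screening bacterial proteome or
    genome collections against a curated catalog of plastic-degrading gene
    products. Implements an affine-gap Smith-Waterman protein search with
    Karlin-Altschul bit-score and E-value statistics, annotated HIT tables,
    unique-hit reduction, genome-normalized counts, polymer-category shares,
    species-by-category degradation-potential scores, neighbor-joining
    clusterization with bootstrap support and nearest-reference subtree
    extraction, plus a deterministic synthetic-collection generator with
    planted homolog families and decoy backgrounds for offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
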