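Package: herbnet
Title: Network Pharmacology Pipeline for Herbal Compound Target
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable network-pharmacology pipeline for
    prioritizing targets of herbal compounds against a disease: rule-based
    ADME compound screening, compound- and disease-target set assembly
    with per-source score filters, protein-protein interaction network
    construction with six-centrality median-rule key-target selection,
    hypergeometric over-representation analysis with Benjamini-Hochberg
    adjustment, heterogeneous compound-target-pathway network degree
    ranking, and post-processing of molecular docking affinities and
    molecular dynamics outputs (RMSD/SASA stability, MM/PBSA energy
    bookkeeping, per-residue decomposition fractions). A synthetic-data
    module generates every pipeline input with known ground truth so each
    stage is verifiable without external database downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
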