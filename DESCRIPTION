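Package: cepin
Title: Condition-Specific Co-Expressed Protein Interaction Networks and
    Dynamic Functional Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrates a static protein-protein interaction network with
    two-condition gene expression profiles to build condition-specific
    co-expressed protein interaction networks (CePINs), identifies
    condition-exclusive functional modules with a two-stage hypergeometric
    enrichment over annotated genes and over "functional dyads"
    (co-expressed interactions whose partners share an annotation) with
    Benjamini-Hochberg false-discovery-rate control, and evaluates modules
    by network topology, sample classification (hierarchical clustering,
    ROC/AUC on module activity scores) and expression-dynamics statistics
    against random-subnetwork nulls. Ships a synthetic-data generator with
    planted co-expression structure so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
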