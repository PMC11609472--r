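Package: clifitree
Title: Directional Class-Based Feature Importance for Tree Ensembles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-tree ensembles for multi-class classification of
    omics feature matrices, with a class-based integrated directional
    feature importance (CLIFI) metric computed during tree construction.
    Implements bagged forests and one-vs-all gradient-boosted trees, both
    optionally with latent-variable ("LAVA") oblique splits driven by a
    feature-interaction graph such as a protein-protein interaction
    network. Includes tools to build feature distance matrices from
    STRING-style edge tables, a planted-signal synthetic data generator,
    stratified evaluation utilities, proximity matrices, and tidy
    exports with ggplot2 visualisations of CLIFI distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    tidyr,
    utils,
    withr
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
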