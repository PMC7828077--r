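Package: walkrank
Title: Propagating Differential Expression Through Heterogeneous
    Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Propagates signed gene-expression fold changes through a
    typed heterogeneous biomedical knowledge graph using gene-restart
    random walks (topic-specific PageRank), embeds each experimental
    comparison as a rank vector over all graph nodes, tests per-node rank
    shifts between comparison groups with Welch's t-test, and retraces
    short explanatory gene-to-node paths for significant nodes.  Includes
    a synthetic knowledge-graph and fold-change generator with planted
    gene-to-phenotype signals so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
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
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
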