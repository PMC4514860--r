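Package: subspia
Title: Subpathway Identification and Impact Analysis for KEGG Signaling Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Locates differentially-expressed-gene (DEG) dense subpathways
    inside KEGG signaling pathways with a weighted minimal-spanning-tree
    construction, scores each subpathway by combining hypergeometric
    enrichment with topology-based perturbation analysis in the style of
    signaling-pathway impact analysis (SPIA), and calls a pathway significant
    when at least one of its subpathways survives false-discovery-rate
    control. Also builds the pathway-level crosstalk network from KGML
    cross-references and summarises the topology (average degree, clustering
    coefficient, betweenness) of an identified pathway set with a
    permutation significance test. Includes a synthetic pathway and DEG
    generator with planted modules so the whole pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
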