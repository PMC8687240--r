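Package: dyspathr
Title: Detecting Dysregulated Pathways from Mutual Exclusivity and
    Mutation-Expression Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Network-based detection of dysregulated pathways from paired
    somatic-mutation and gene-expression cohorts. Builds an undirected gene
    network from pairwise mutual exclusivity of mutations (exclusive-degree
    and weight-degree thresholds) and from a mutation-to-expression
    connectivity criterion, enumerates cliques in the network, and
    iteratively merges overlapping cliques by a squared-intersection overlap
    score into candidate dysregulated pathways. Includes readers and writers
    for dense sample-by-gene matrices, a synthetic-cohort generator with
    planted mutually exclusive pathways and mutation-driven expression
    shifts for ground-truth recovery testing, broom-style tidiers, ggplot2
    autoplot methods, and an end-to-end pipeline with reproducible reports.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
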