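Package: dcsmine
Title: Mining Top-k Overlapping Densest Connected Subgraphs in Dual Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for finding the top-k weighted overlapping densest connected
    subgraphs (DCS) in a dual network, i.e. a pair of graphs over one node
    universe in which an unweighted "physical" graph carries connectivity and a
    weighted "conceptual" graph carries relation strength. A two-step pipeline
    first merges the pair into a single weighted alignment graph that preserves
    physical connectivity, then mines it with the IWDS heuristic built on
    V-Greedy, a correction-factor variant of the classic greedy peeling
    1/2-approximation for the weighted densest subgraph. Includes planted-clique
    synthetic benchmark generators (disjoint and cyclically overlapping, with a
    controlled noise procedure), best-matching F1 evaluation of detected versus
    ground-truth subgraphs, and a seeded experiment harness. Edge lists go in
    and tibbles come out, so results compose with the tidyverse.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
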