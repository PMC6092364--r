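Package: fluxgraphs
Title: Flux-Based Graphs for Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of flux-based graphs derived from
    genome-scale metabolic models. Builds the Reaction Adjacency Graph, the
    Normalised Flow Graph (a probabilistic, directed blueprint of metabolism
    that naturally down-weights pool metabolites), context-specific Mass Flow
    Graphs computed from Flux Balance Analysis solutions, and competition and
    synergy graphs. Includes a bounded-variable simplex solver for the FBA
    linear programme, PageRank centrality with teleportation on weighted
    directed graphs, and multiscale community detection by Markov Stability
    with variation-of-information robustness analysis.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    xml2,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
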