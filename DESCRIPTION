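Package: morphonet
Title: Anatomical Network Analysis of Arthropod Metamorphosis
Version: 0.1.0
Authors@R:
    person("morphonet", "maintainers", email = "morphonet@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling external morphology as undirected binary
    networks and for analysing how network organisation changes across an
    ontogenetic series. Provides readers and writers for adjacency-matrix
    files, classical network parameter tables, multi-level (Louvain)
    modularity with within-module degree / participation-coefficient node
    roles, topological-overlap hierarchy trees, a battery of normalised
    graph complexity measures (medium articulation, efficiency and graph
    index complexity, offdiagonal complexity, spanning-tree sensitivity,
    one-edge-deleted subgraph complexity), four families of topological
    descriptors, connected degree-sequence-preserving null models,
    robustness analyses (global efficiency, vulnerability, rich core,
    error and attack tolerance), a synthetic body-plan network generator,
    and a pipeline that classifies measures into intensive and extensive
    trends across development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
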