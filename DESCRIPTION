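Package: stnet
Title: Reachability, Centrality and Robustness in Spatio-Temporal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models time-varying, spatially embedded networks in which
    propagation between nodes is non-instantaneous and constrained by
    inter-node distance and time-varying propagation speed. Provides a
    discrete-time constrained-propagation engine, spatio-temporal shortest
    paths and distances, temporal in-closeness, path-betweenness and
    betweenness-efficiency centralities, descriptive statistics for
    snapshot sequences, and robustness analysis of the giant strongly
    connected component and temporal/spatial efficiency under random node
    failure and systematic attack. Includes seeded generators for
    transit-schedule, flight-like, connectome-like and contact-network
    synthetic systems, plus plain-text loaders for node, trajectory and
    snapshot edge tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Matrix,
    igraph,
    jsonlite,
    geosphere,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
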