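Package: sosbn
Title: Bayesian Network Analysis of Sedentary-Behaviour Determinants
Version: 0.1.0
Authors@R:
    person("sosbn", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: System-based analysis of the determinants of sedentary
    behaviour (SB) with discrete Bayesian networks. Provides a synthetic
    generator for Eurobarometer-like categorical survey data from a known
    ground-truth network, the full set of variable operationalisation
    rules aligned to the SOS-framework (Systems of Sedentary Behaviours),
    hybrid constraint/score structure learning implemented from scratch
    (G-squared conditional-independence tests, BIC scoring, PC-stable
    skeleton, hill climbing), bootstrap edge-stability model averaging,
    and the network statistics used to rank factors around SB: denseness,
    unweighted distance to SB, per-cluster mean distance, and
    stability-weighted betweenness centrality on the SB-linked subgraph.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
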