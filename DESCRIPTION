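Package: lccontrol
Title: Minimum Input Node Placement with Longest Control Chain Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the longest-control-chain (LCC) constrained minimum
    input problem of structural network controllability: given a directed
    network, find a minimum set of input nodes such that the system is
    structurally controllable and every node is within a prescribed distance
    of an input. Provides exact solvers (integer linear programming and
    exhaustive search), a coupled matching/dominating-set leaf-removal
    approximation with core-percolation diagnostics, matching- and
    domination-based bounds, Erdos-Renyi and static scale-free network
    generators with degree-preserving randomization, finite-time
    controllability Gramian energy computations, and scripted ensemble
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
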