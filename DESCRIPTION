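Package: boolcontrol
Title: Influence Maximization and Pinning Control of Boolean Networks
Version: 0.1.0
Authors@R:
    person("R.", "Keller", email = "rkeller@example.org", role = c("aut", "cre"))
Description: Tools to identify minimal sets of driver nodes that steer the
    long-term dynamics of Boolean networks, such as models of gene regulation
    and cell signaling, toward a desired attractor. Provides exact synchronous
    (and asynchronous) simulation, brute-force state-transition-graph and
    attractor/basin analysis for small systems, an individual-based mean-field
    approximation (IBMFA) of the average dynamics of a quenched Boolean
    network, an entropy measure of the dynamical influence of pinned seed
    sets, and greedy (constrained and unconstrained) selection of
    quasi-minimal driver sets with post-processing. Includes generators for
    random Boolean networks, transcriptions of published gene regulatory
    network models for validation, readers and writers for BoolNet-style rule
    files and a lossless JSON schema, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
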