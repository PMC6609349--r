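Package: pmnet
Title: Producibility Metrics for Stoichiometric Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Percolation-inspired, probabilistic analysis of metabolite
    producibility in stoichiometric metabolic networks. Estimates how robustly
    a network synthesizes a target metabolite under Bernoulli-sampled input
    environments (the producibility metric, PM = 1 - P_in,0.5), with an exact
    combinatorial counterpart based on minimal precursor sets for small
    candidate pools. Includes readers for SBML (Level 3 + FBC) and COBRA JSON
    models, linear-programming feasibility with equality or inequality mass
    balance, flux balance analysis, random reaction-removal robustness
    experiments, gene knockouts, pairwise inter-organism metrics (PM distance
    and complementarity, seed-set metrics, reaction distances), and Mantel /
    partial Mantel permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    xml2,
    readr,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    boot,
    vegan,
    optparse
Config/testthat/edition: 3
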