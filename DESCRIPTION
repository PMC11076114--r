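Package: poolflow
Title: Ribosome Flow Model Networks with Finite Particle Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of networks of ribosome flow models
    (RFMs) coupled through finite pools of free particles. Several
    one-dimensional excluded-flow lanes draw their entry flux from, and
    return their output to, shared pools, so the lanes compete for a
    conserved number of particles. The package assembles and integrates
    the network ODEs (constant or periodic transition rates), computes
    steady states either by relaxation with Newton refinement or by a
    spectral route based on Perron eigenpairs of per-lane Jacobi matrices,
    classifies the network-wide effect of perturbing a single transition
    rate, and cross-validates the mean-field model against a
    continuous-time exclusion-process Monte Carlo simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
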