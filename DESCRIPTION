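Package: momentinfer
Title: Moment-Based Inference for Stochastic Chemical Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic generation of moment-closure (2MA, 3MA) and
    system-size-expansion (RRE, LNA, EMRE, IOS) ordinary differential
    equation systems with forward sensitivities from mass-action reaction
    network descriptions, and their use for gradient-based maximum
    likelihood estimation from population-average or single-cell snapshot
    data. Includes an exact stochastic simulation algorithm (Gillespie
    direct method) for synthetic data generation, profile-likelihood and
    delayed-rejection adaptive Metropolis MCMC uncertainty analysis, AIC
    and BIC model selection, chi-square model rejection, and built-in
    benchmark networks for in-silico estimation-error studies across
    reaction volumes and sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0), xml2, Matrix
Config/testthat/edition: 3
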