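Package: castevol
Title: Comparative Phylogenetics of Reproductive Division of Labour
Version: 0.1.0
Authors@R: person("Packaged", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the evolution of reproductive division of
    labour in social insects with comparative phylogenetic methods:
    constrained multistate Markov (Mk) models of discrete trait evolution
    fitted by maximum likelihood and MCMC, stepping-stone marginal
    likelihoods and Bayes factors, Pagel's test of correlated evolution for
    binary trait pairs, marginal ancestral state reconstruction with
    transition counting (joint and stochastic mapping), Brownian-motion
    ancestral estimates for continuous traits, phylogenetic generalized
    least squares, Bayesian phylogenetic mixed models, and phylogenetic path
    analysis via d-separation (Fisher's C and CICc). A synthetic-data module
    simulates birth-death trees, discrete and continuous traits, and
    causally linked trait sets with full ground truth so that every stage of
    the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
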