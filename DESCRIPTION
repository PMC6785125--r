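Package: cdtem
Title: Coalescent Demographic Inference and Molecular-Rate Calibration by
    Demographic Transition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the recent demographic history of a
    single-locus (typically mitochondrial) population sample. Implements
    two-epoch coalescent demographic models (constant ancient size followed
    by exponential or logistic growth), Bayesian Markov chain Monte Carlo
    inference of the model under an HKY+Gamma substitution model with
    strict or uncorrelated relaxed clocks, marginal-likelihood model
    comparison, calibration of the demographic transition against a
    temperature proxy record to obtain a stochastic substitution-rate
    distribution, piecewise-linear Bayesian skyline reconstruction, maximum
    clade credibility trees, and population split-time posteriors.
    Includes standard mitochondrial summary statistics (haplotype and
    nucleotide diversity, Tajima's D, Fu's Fs, R2, pairwise Phi-st with
    permutation tests, Tamura 1992 + Gamma distances, minimum spanning
    haplotype networks) and a coalescent simulator used both for synthetic
    data generation and for neutrality-test null distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
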