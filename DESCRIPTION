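Package: ssrabc
Title: Microsatellite Population Genetics and Approximate Bayesian
    Computation for Highly Selfing Weeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping the origins and spread of herbicide
    resistance in highly self-fertilizing weed populations from diploid
    microsatellite genotypes.  Reads and writes GenePop and delimited
    genotype tables with polyploid-profile quality control; computes
    Weir-Cockerham F-statistics, allelic richness by rarefaction,
    selfing rates, Nei (1972) distances, Garza-Williamson M, assignment
    likelihoods and shared-allele distances; identifies and classifies
    multilocus genotypes (selfing lineages) as nonrecombinant,
    single-step mutational variants or recombinants; summarizes
    herbicide-assay survival and its correlation with a county covariate;
    and performs coalescent-based approximate Bayesian computation
    (generalized stepwise mutation model, scenario choice by local
    logistic regression, confidence-in-choice error rates, Beaumont
    regression-adjusted parameter estimation, and posterior predictive
    model checking).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nnet,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
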