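Package: MultiTraitGP
Title: Multi-Trait Bayesian Genomic Prediction for Augmented Wheat Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trait and multi-trait Bayesian genomic prediction (GBLUP with
    a genomic relationship matrix, Gibbs sampling with Kronecker-structured
    genetic covariance) for plant breeding panels evaluated in augmented
    multi-environment trials. Provides phenotype adjustment (BLUEs) with an
    anthesis-date covariate, broad-sense heritability from variance components,
    VanRaden additive relationship matrices from -1/0/+1 coded markers with
    missing-value imputation, Monte-Carlo cross-validation schemes CV1 and CV2
    for comparing single- and multi-trait predictive ability, and a synthetic
    data generator that emulates the statistical structure of a wheat line
    panel with correlated primary and secondary (physiological) traits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    lme4,
    Rcpp,
    vcfR,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'blues.R'
    'crossval.R'
    'gibbs.R'
    'io.R'
    'kinship.R'
    'simulate.R'
    'pipeline.R'
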