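Package: gshybrid
Title: Genomic Prediction Evaluation for Two-Species Hybrid Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for genomic selection in
    interspecific hybrid breeding populations of the Eucalyptus type: two
    diverged parental species crossed in an incomplete diallel to produce F1
    full-sib families. Provides a synthetic population generator
    (Balding-Nichols species divergence, Markov haplotype-copying LD,
    recombination by the Haldane map, pedigree-error injection, additive
    traits at target heritabilities), SNP quality control (call rate, MAF,
    exact Hardy-Weinberg test, LD pruning, Hill-Weir LD-decay fitting),
    pedigree and VanRaden genomic relationship matrices, five prediction
    engines (ABLUP, GBLUP, rrBLUP, Bayesian LASSO, Gaussian multi-kernel
    RKHS), REML variance components and heritability, and relatedness-aware
    cross-validation designs with predictive-ability grids over training-set
    sizes, SNP numbers and SNP genomic location.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    tibble,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
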