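Package: labshdmr
Title: Block Second-Order HDMR Classification and Pairwise Interaction
    Detection for SNP Dosage Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary case/control classification of categorical SNP dosage
    data via a block-approximated second-order high dimensional model
    representation (HDMR) of the log-likelihood ratio (LABS-HDMR-CO),
    together with the Fixed Pattern Test (FPT) for detecting pairwise SNP
    interaction patterns as class-dependent indicator correlations, an
    exact HDMR expansion and Sobol-index calculator for fully enumerable
    categorical joints, a Dirichlet-multinomial Bayesian feature filter,
    and a Gaussian-copula case/control genotype simulator with
    linkage-disequilibrium blocks, additive effects, and planted
    pairwise-interaction patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
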