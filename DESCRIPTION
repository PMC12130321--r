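Package: nnpgs
Title: Neural-Network Versus Additive Polygenic Score Comparison Framework
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and evaluation framework for quantifying how much
    genuine nonlinearity (gene-gene and gene-environment interaction) neural
    networks can exploit for polygenic prediction, and for separating that
    signal from the joint-tagging artefacts created by linkage
    disequilibrium. Provides a seedable latent-Gaussian genotype simulator
    with block LD structure, a phenotype generator with additive, four-way
    epistatic, blended and environmental architectures, GWAS and LD-aware
    additive polygenic score baselines, matched linear and nonlinear
    multilayer perceptrons with a linear-collapse verification, two
    joint-tagging mitigation strategies (SNP-dosage weighting and LD
    clumping plus distance filtering), and paired-replicate comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
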