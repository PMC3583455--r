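Package: gsalloc
Title: Resource Allocation for Genomic Selection in Biparental Doubled-Haploid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how a fixed field-plot budget should
    be split between population size and phenotypic replication when training
    genomic selection models in a biparental doubled-haploid (DH) population.
    Provides a maize-like genome and meiosis simulator (Poisson crossovers, no
    interference), DH line production and random mating, plot-level phenotype
    simulation under a target plot heritability, three marker-effect models
    (ridge-regression BLUP with spectral-decomposition REML, BayesC-pi Gibbs
    sampling, and forward-backward stepwise ordinary least squares), deterministic
    expected-accuracy formulas based on the effective number of chromosome
    segments, and replicated experiment drivers for cross-validation accuracy
    grids, budget tradeoff grids, theory-versus-simulation comparison, accuracy
    decay under random mating, and multi-cycle recurrent genomic selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
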