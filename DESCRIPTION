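Package: icbreedsim
Title: Stochastic Simulation of Intercrop Breeding Schemes for Self-Pollinating Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of multi-stage line-breeding programs for a
    binary cereal-legume intercropping system. Simulates founder haplotypes,
    correlated monocrop and intercrop additive trait architectures, Mendelian
    gamete formation with Haldane recombination, doubled-haploid and
    ear/pod-to-row line fixation, and truncation selection through preliminary,
    advanced and elite yield trials under fixed plot budgets. Quantifies the
    genetic progress of intercrop performance as a function of trait
    heritability, the monocrop-intercrop genetic correlation, and the stage at
    which phenotypic testing switches from monocrop plots to intercrop
    combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
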