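Package: surrosire
Title: Stochastic Simulation of Surrogate Sire Strategies in Livestock
    Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Gene-drop simulation of a two-part pig breeding program: a
    genomic-selection nucleus supplies commercial sires either through
    conventional multiplication (with genetic-lag dilution by unselected
    multiplier females) or through surrogate sires carrying the germline
    of elite donors identified by multi-stage testing (a genomic screen
    followed by one or two progeny tests under a fixed progeny budget).
    Provides founder-haplotype generation, meiosis with Poisson
    recombination, additive trait architectures, pseudo-estimated
    breeding values at targeted accuracies, selection-theory utilities,
    commercial-sire merit trajectories, and comparison of strategies in
    years' worth of genetic gain across replicated experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    vcfR
LinkingTo:
    Rcpp
VignetteBuilder:
    knitr
Config/testthat/edition: 3
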