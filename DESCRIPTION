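Package: regou
Title: Phylogenetic ANCOVA with Ornstein-Uhlenbeck Residual Transforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits ANCOVA-style regressions of a continuous species trait
    (hematocrit, in percent packed cell volume) on dummy-coded habitat and
    clade factors under three residual-covariance models: ordinary least
    squares (star phylogeny), phylogenetic generalized least squares under
    Brownian motion, and a regression with an Ornstein-Uhlenbeck
    branch-length transformation of the tree indexed by a parameter d
    estimated by restricted maximum likelihood. Provides maximum-likelihood
    model comparison via AICc with Burnham-Anderson support labels, partial
    F-tests for factor blocks, likelihood-ratio tests for phylogenetic
    signal, Pagel arbitrary branch-length assignment for topologies without
    measured lengths, and a seeded synthetic-data generator (Yule trees,
    Markov habitat walks, multivariate-normal trait simulation) for
    end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
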