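Package: dynblup
Title: Dynamical BLUP Simulation of Reaction-Norm Evolution in Changing
    Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of linear reaction norms (intercepts and
    plasticity slopes for multiple traits and environmental cues) in a
    population tracking moving fitness peaks, and estimates individual
    additive-genetic deviations each generation with a dynamical best linear
    unbiased prediction (BLUP) model whose incidence and residual covariance
    matrices follow the environmental cues. Mean reaction-norm parameters are
    updated between generations via Robertson's secondary theorem of natural
    selection applied to the BLUP random effects, with comparator update
    rules (selection-gradient form and the multivariate breeder's equation),
    support for genetic relatedness through the additive genetic relationship
    matrix, and overlapping-generations scaling. Includes a stochastic
    environment generator, drift diagnostics, and tidy tabular outputs with
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
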