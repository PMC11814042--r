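Package: sourcerisk
Title: Source Apportionment and Probabilistic Health Risk for Soil Geochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for multi-element soil surveys around
    industrial and mining sites. Computes soil-property-adjusted target and
    intervention values, Hakanson ecological risk indices, centred log-ratio
    (clr) compositional biplots with k-means clustering, signed element
    association networks with expected-influence centrality, varimax-rotated
    principal components, and a from-scratch uncertainty-weighted positive
    matrix factorisation (PMF) receptor model. Total and source-apportioned
    concentrations feed a USEPA-style multi-route health risk assessment
    (hazard quotients and index, carcinogenic risk) evaluated both
    deterministically and by Monte Carlo simulation, including per-factor
    source-oriented risk. A synthetic-data generator with a known
    source-mixing structure makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
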