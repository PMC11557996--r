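Package: carapace
Title: Phylogenetic Evolutionary Allometry and Body-Size Estimation in Turtles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Phylogenetic generalized least squares (PGLS) regression with
    jointly estimated Pagel's lambda, small-sample Akaike model selection with
    binary ecological and clade covariates, bootstrap confidence intervals,
    Brownian-motion evolutionary rate (sigma-squared) estimation with
    measurement error, specimen maturity filtering, and shell-length /
    body-mass prediction equations for fossil turtles. Includes a
    synthetic-data generator (Yule trees, Brownian traits with a log-log
    allometric link and lambda-structured residuals, specimen-level
    ontogenetic and sex structure) so the whole pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phytools,
    MASS,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
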