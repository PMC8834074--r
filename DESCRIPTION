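Package: qdgame
Title: Quasi-Dynamic ODE Game Models of Cell-Cell Crosstalk from Static Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts static paired expression data into quasi-dynamic ordinary
    differential equation (qdODE) systems indexed by a niche or expression
    index, decomposes each gene's (or cell's) expression trajectory into an
    independent power-law component and dependent Legendre-polynomial
    components, tests and classifies directional cell-cell interactions
    (synergism, antagonism, altruism, coexistence) with a permutation
    likelihood-ratio test under bivariate AR(1) errors, and recovers sparse
    signed, weighted, directed gene and cell networks with per-node hubness
    scores. Includes a synthetic-data generator emulating paired two-cell-type
    designs so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    readr,
    Matrix,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
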