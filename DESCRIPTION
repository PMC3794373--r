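Package: netevolve
Title: Growing Networks with Internal Links and Node and Edge Deletion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates and solves a minimal model of network evolution in
    which four elementary processes act simultaneously: external attachment
    of new nodes (random plus degree-preferential), addition of internal
    edges between existing nodes, uniform node deletion, and uniform edge
    deletion. Provides a fast stochastic simulator, a numerical solver of
    the stationary degree-distribution rate equation under the uncorrelated
    factorization, closed-form predictions for the mean degree, degree
    exponent, small-degree shift and exponential correction factor, the
    exponential/power-law phase diagram with its critical boundaries, and
    maximum-likelihood fitting of empirical degree tails to shifted power
    laws and exponentially corrected power laws.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
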