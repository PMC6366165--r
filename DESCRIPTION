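Package: dispersim
Title: Spatially Explicit Agent-Based Simulation of Animal Dispersal in
    Fragmented Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the transience stage of animal dispersal through
    fragmented landscapes with a spatially explicit agent-based model.
    Generates neutral landscapes controlled by habitat amount and
    aggregation, moves agents by a correlated random walk with a forward
    perceptual window, per-step mortality, matrix foraging and
    minimum-area settlement rules, and aggregates cohorts into dispersal
    success proportions. Includes trait trade-off ("broken-stick" budget)
    experiments on the five-trait investment simplex, Latin hypercube
    exploration of the parameter space, boosted-regression-tree relative
    influence analysis, and quantile-regression payoff ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    lhs,
    xgboost,
    quantreg,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
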