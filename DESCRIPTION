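Package: egnb
Title: Evolutionary Games on Networks for Brain Activity Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and identification of a replicator-equation model of
    inter-regional brain activation dynamics. Each brain region is a player in
    a two-strategy (activation/inactivation) game whose emulative or
    non-emulative attitude towards its neighbours is encoded in the sign of a
    connectivity matrix. The package integrates the resulting replicator
    equation on graphs, estimates the signed connectivity matrix from
    BOLD-like multivariate time series by linear least squares, evaluates
    forward predictive power against a linear baseline, and simulates
    in-silico node lesions with functional-connectivity response analysis.
    A synthetic-data generator produces modular ground-truth networks and
    noisy model trajectories for validation without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
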