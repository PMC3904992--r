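Package: shgame
Title: Spatial Social Honesty Game Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.com")
Description: Simulates the Social Honesty game, a two-strategy (honest vs
    dishonest) spatial evolutionary game with stochastic payoffs and
    probabilistic punishment of dishonest players. Provides periodic-lattice
    (Moore, von Neumann), well-mixed and scale-free interaction topologies,
    synchronous imitation dynamics (best-neighbor, myopic and Fermi update
    rules), and analysis tools for honest-rate dynamics, punishment
    probability and severity sweeps, phase-transition intervals, critical
    punishment probabilities, and a row-scan cluster granularity statistic.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
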