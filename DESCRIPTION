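Package: trapsim
Title: Forward Simulation of Transposable Element Invasions Under the
    piRNA Cluster Trap Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-based forward-time simulation of transposable
    element (TE) invasions in diploid host populations in which piRNA
    clusters act as genomic traps: a single TE insertion inside a cluster
    silences all copies of the family in trans. Provides the generation
    engine (fitness-proportional mate choice, recombination on a
    centimorgan map, Poisson transposition with trap silencing), four
    fitness models (linear, dominance, epistatic, heterogeneous per-site
    effects), scenario presets and random parameter sweeps, outcome
    classification (extinction, TE loss, stable control), summary
    statistics such as the minimum population fitness and the largest
    piRNA cluster among extinct populations, and closed-form oracles used
    to validate the stochastic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
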