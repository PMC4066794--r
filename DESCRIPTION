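Package: sseDrive
Title: Stochastic Population Dynamics and Homing-Assay Estimation for
    Synthetic Selfish Elements
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the spread of homing-based synthetic selfish elements
    (nuclease gene drives) through randomly mating insect populations. The
    package implements a four-allele model of drive inheritance -- cleavable
    target (T), drive-capable donor (D), non-functional homed donor (DN) and
    end-joining resistance allele (N) -- as both a stochastic discrete-
    generation simulator and its deterministic infinite-population
    expectation recursion. It also provides the companion laboratory
    readouts: marker-based classification of cross progeny, estimation of
    cleavage, homing and functional-homing rates with Wilson score
    confidence intervals, chi-square tests of 1:1 Mendelian segregation, and
    a synthetic-data generator so that every stage of the pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, PopulationGenetics, Software
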