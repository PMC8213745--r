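Package: peernorms
Title: Simulation and Analysis of Peer-Norm Conformity in Classroom Networks
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-wave peer-influence experiments on personal norms
    in classroom social networks. Generates synthetic classrooms with
    popularity-nomination networks and 1-11 rating-scale data, identifies
    normative sources (classroom majority mode and top-five most-nominated
    peers), builds counterbalanced wave-2 trial designs with controlled
    normative-information distance, computes the norm-adjustment weight
    S = (P2 - P1)/(NI - P1) with exclusion and strategy-classification rules,
    and fits the pre-specified random-intercept linear and logistic mixed
    models. A seeded command-line pipeline orchestrates generation, design,
    simulation, scoring and inference with plain-CSV interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    optparse,
    numDeriv,
    statmod,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
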