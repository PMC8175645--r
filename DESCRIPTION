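Package: pathrisk
Title: Patient-Journey Knowledge Graphs and Intra-Hospital Risk Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Collects structured intra-hospital patient journeys (admission
    condition, ordered care steps, discharge state) into cluster-indexed
    directed graphs and interrogates them as absorbing Markov chains:
    outcome-probability profiles and the risk of missing the expected
    outcome from any stage, next-step probability distributions, and
    alignment of realized journeys against planned clinical pathways with
    a three-way deviation typology (reroute, insertion, unintended
    outcome). Includes a seeded first-order Markov journey simulator with
    deviation injection for parameter-recovery testing, a pluggable
    supervised risk predictor for patients outside the closed-world
    knowledge base, JSON-Lines journey-log serialization, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
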