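Package: dietrhythm
Title: Temporal Diet Quality, Dietary Regularity, and Gut Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Food Log", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline linking longitudinal food-log data to gut microbiome
    profiles. Computes diet-quality scores (Healthy Eating Index 2020, both the
    standard across-day form and a day-wise averaged form), day-to-day dietary
    regularity as coefficients of variation, dietary diversity indices,
    microbiome alpha and beta diversity (Shannon, Pielou, observed features,
    Faith's phylogenetic diversity, unweighted UniFrac, principal coordinates),
    compositional log-ratio reference frames from per-taxon differential
    effects, covariate-adjusted association testing with false discovery rate
    control, stool-quality feature derivation, and a bidirectional
    gradient-boosting prediction harness. Ships a seeded synthetic cohort
    generator with planted diet-microbiome effects so the whole pipeline is
    testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
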