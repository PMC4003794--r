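Package: fuzzboost
Title: Boosted Fuzzy Rule Extraction with Discrete Particle Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns compact sets of interpretable fuzzy if-then rules for
    binary classification of tabular clinical records. Candidate rules are
    encoded over a 15-symbol alphabet of triangular fuzzy partitions of the
    unit interval and searched by a discrete particle swarm whose velocities
    are sequences of rule-antecedent substitutions. A boosting scheme
    multiplicatively down-weights training instances covered by accepted
    rules so that successive swarm runs focus on uncovered or misclassified
    records. Includes a reader for the UCI heart-disease record layout, a
    planted-rule synthetic data generator, winner-rule inference weighted by
    per-rule certainty factors, confusion-matrix metrics, and stratified
    k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
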