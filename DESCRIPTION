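Package: vbsphen
Title: Multidimensional Behavioral Phenotyping of Group-Housed Rats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multidimensional behavioral phenotyping of
    rats living in groups inside an automated visible burrow system (VBS).
    From RFID detection streams, scan-sampled dyadic ethogram events, operant
    task logs and physiological measures it computes spatial metrics (activity,
    roaming entropy, place preference), directed weighted social-network
    metrics, Glicko-rating dominance hierarchies with online Bayesian
    change-point detection, Blanchard dominance scores, decision-making and
    discounting scores, and assembles a per-animal feature table for
    unsupervised genotype discrimination (random-forest Gini importance with
    leave-one-out cross-validation, k-means clustering of importances, and
    principal component analysis). A synthetic-colony generator with
    configurable genotype effect sizes makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
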