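Package: forageadapt
Title: Forage Germplasm Performance Evaluation and Introduction
    Adaptability Prediction
Version: 0.1.0
Authors@R:
    person("Forage", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating the forage production performance of
    crop germplasm collections and for predicting where candidate
    germplasms can be introduced.  The trait side covers descriptive and
    variation statistics, Shannon trait diversity, entropy weighting,
    grey relational analysis, ridge-regression path analysis, PCA trait
    contributions, fuzzy membership-function comprehensive scoring and
    hierarchical cluster cuts.  The geographic side covers a desk-scale
    ensemble species distribution model (occurrence cleaning and
    rarefaction, collinearity filtering, pseudo-absence sampling,
    multi-learner fitting with repeated holdout, AUC-weighted consensus,
    TSS/Kappa/AUC evaluation, permutation variable importance), Fisher-
    Jenks natural-breaks suitability classification, per-region area
    accounting on the sphere, suitability-centroid migration, Mantel
    permutation tests and an environmental-similarity adaptability
    matrix.  A seeded synthetic-data generator provides trait tables,
    environmental landscapes, occurrences and region polygons with known
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    mgcv,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
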