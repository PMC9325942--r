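Package: cogshap
Title: Reliability and Stability of Shapley Markers of Cognitive Decline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end framework for assessing the reliability and stability
    of local Shapley (SHAP) attribution markers in three-class cognitive-status
    classification (normal control, mild cognitive impairment, Alzheimer's
    dementia) from cognitive and clinical indexes. Provides a synthetic
    longitudinal cohort generator with class-conditional Gaussian index
    distributions and stable/converter trajectories; a class-balanced
    undersampling random-forest ensemble with leave-one-subject-out or grouped
    k-fold cross-validation, nested hyperparameter search and probability
    averaging; exact (full coalition enumeration) and Monte Carlo Shapley
    attribution; cross-sectional similarity-network analysis of attribution
    vectors (cosine distances, ANOVA with post-hoc comparisons, bootstrap
    Jaccard clusterwise stability of k-medoid partitions); and a retrospective
    longitudinal analysis (first-versus-last-visit attribution distances,
    trajectory classes, ANCOVA, permutation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
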