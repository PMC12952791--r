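Package: ethokit
Title: Behavior Phenotyping from Pose Keypoints for the Laboratory Mouse
Version: 0.1.0
Authors@R:
    person("Ethokit", "Developers", email = "ethokit@example.org", role = c("aut", "cre"))
Description: Tools for supervised behavior classification and strain-level
    phenotyping of laboratory mice from pose-estimation keypoints. Reads and
    writes a documented HDF5 pose dialect (12 keypoints per frame), computes
    per-frame kinematic features and sliding-window summary features, trains
    tree-ensemble classifiers (random forest and gradient boosting,
    implemented natively) from sparse frame labels with grouped cross
    validation, and post-processes predicted ethograms by bout stitching and
    filtering. Provides frame-level agreement statistics (confusion counts,
    Cohen's kappa, ROC/AUROC, TPR at fixed FPR), a bipartite bout-graph
    ("ethograph") framework for bout-level agreement between annotators or
    classifiers, aggregate phenotype construction with z-scoring and
    nonparametric sex-effect testing, dataset imbalance metrics, and a
    genetics toolkit: genotype QC, single-marker association scans,
    permutation significance thresholds, GWAS power simulation, greedy
    LD-based QTL grouping, and Haseman-Elston estimators of SNP heritability
    and genetic correlation. Seeded synthetic-data generators produce pose
    sequences with scripted behaviors, annotator-pair label noise, and strain
    panels with known genetic architecture for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rhdf5,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
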