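Package: mrsdm
Title: Multi-Realm Species Distribution Models Across the Land-Sea Boundary
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits, validates and ensembles species distribution models (SDMs)
    for species that depend on both the terrestrial and the marine realm, such
    as breeding seabirds. Environmental layers from the two realms are combined
    into single-model covariate tables: terrestrial cells receive the mean and
    standard deviation of marine conditions within a foraging-distance buffer
    around the nearest coastal cell, and marine cells inherit the values of
    their nearest terrestrial cell. Includes distance-to-coast covariates with
    a coastal-zero rule, landmass area and isolation, constrained pseudo-absence
    sampling, collinearity screening with variable-set permutations, a pluggable
    learner layer (logistic GLM, random forest, neural network, optional GAM),
    repeated internal validation with threshold-optimised true skill statistic
    (TSS) and ROC AUC, permutation variable importance, and a TSS-gated,
    TSS-weighted ensemble projection with across-model variance. A synthetic
    seascape and virtual-species generator supports fully reproducible,
    download-free experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    igraph,
    randomForest,
    nnet,
    mgcv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    pROC,
    knitr
Config/testthat/edition: 3
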