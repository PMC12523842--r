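Package: sauryhab
Title: Ensemble Species Distribution Modelling of Pacific Saury Habitat from Vessel Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end habitat analysis pipeline for the Pacific saury
    (Cololabis saira) fishery in the North Pacific high seas: extraction of
    fishing-operation points from vessel (AIS-style) trajectories with a
    conservative threshold rule set, grid-cell spatial thinning and background
    (pseudo-absence) sampling, an ensemble species distribution model with
    TSS-weighted model averaging over a pluggable base-learner registry,
    cross-validated skill evaluation (TSS, AUC, sensitivity, specificity),
    permutation variable importance and response curves, and projection onto
    climate-scenario environmental stacks with habitat zonation, transition
    mapping and great-circle centroid-shift quantification. Includes a
    synthetic-data module (environmental stacks with a known niche, scenario
    deltas, and state-labelled vessel trajectories) so every stage is testable
    against ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    ranger,
    xgboost,
    nnet,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ncdf4,
    geosphere,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
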