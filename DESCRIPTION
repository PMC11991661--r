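Package: sdmstack
Title: Ensemble Species Distribution Modeling and Stacked Richness Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for ensemble (consensus) species distribution
    modeling and stacked species richness analysis: occurrence cleaning by
    grid thinning and minimum-record filtering, pairwise-correlation variable
    selection, pseudo-absence sampling, replicated train/test model fitting
    over a pluggable learner registry (with a native surface range envelope
    learner), TSS/Kappa/AUC evaluation, TSS-gated and TSS-weighted ensemble
    prediction with permutation variable importance, occurrence-anchored
    binarization, multi-species richness stacking with category area
    accounting on the sphere, Jenks natural-breaks suitability tiers, and
    range-centroid migration (great-circle distance and bearing). Includes a
    seeded virtual-species benchmark generator so every stage is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    MASS,
    mgcv,
    nnet,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
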