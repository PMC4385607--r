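Package: lbptex
Title: Local Binary Pattern Texture Analysis for Brain MRI Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rotation-invariant local binary pattern (LBP) and local-contrast
    texture analysis of brain magnetic resonance volumes inside white-matter
    and white-matter-lesion regions of interest, with slice-wise
    histogram-mode threshold segmentation of white-matter hyperintensities,
    48-feature per-subject texture summaries, SMOTE class rebalancing, and
    nested cross-validation with best-first wrapper feature selection around
    a small random-forest ensemble. Includes a synthetic cohort generator
    producing MRI-like volumes with controllable class-dependent texture so
    the whole pipeline can be exercised and calibrated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    randomForest,
    rlang,
    RNifti,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
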