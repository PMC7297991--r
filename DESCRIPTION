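Package: fetalgrowth
Title: Sex Differences in Fetal Brain Growth Trajectories from Repeated Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying male-female differences in fetal brain
    growth from repeated morphometric measures. Fits log-domain polynomial
    mixed-effects growth models with subject random effects, relative
    (global-covaried) growth models, and regression-based left-right
    asymmetry tests, reporting sex effects as percent differences at a
    reference gestational week with parametric-bootstrap confidence
    intervals and Bonferroni flags. Includes voxelwise tensor-based
    morphometry of Jacobian-determinant maps with maxT permutation
    family-wise error control, labelled-mesh surface area and quadric-fit
    mean-curvature summaries, and a synthetic-cohort generator that
    reproduces the sampling structure of a longitudinal fetal MRI study so
    every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    lmtest,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
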