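Package: stirq
Title: Predicting Quantitative Muscle MRI Biomarkers from STIR Radiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting per-muscle fat fraction (FF, percentage
    points) and water T2 (wT2, ms) of calf muscles from conventional
    short-tau inversion recovery (STIR) magnetic resonance slices. The
    package provides a seeded phantom generator for healthy-control and
    FSHD-like cohorts with known ground truth, histogram-matching intensity
    harmonization, an IBSI-style 56-feature radiomic catalog (first-order,
    GLCM, GLZLM, GLRLM and shape features), three feature workflows
    (principal components; information-imbalance feature-subset selection;
    healthy-reference fat-infiltration and muscle-edema grades), seven
    regression models under 5-fold cross-validation, and mean-absolute-error
    and coefficient-of-variation evaluation with correlation screens.
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
    glmnet,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    rlang (>= 1.0.0),
    RNifti,
    rpart,
    e1071,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    caret,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
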