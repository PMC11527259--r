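Package: fibroscore
Title: Deep-Feature Fibrosis Scoring of Systemic Sclerosis Skin Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative scoring of dermal fibrosis in systemic sclerosis
    (SSc) skin biopsies. Implements random dermis-restricted patch sampling
    from trichrome-stained whole-slide rasters, fixed-length quantitative
    image feature (QIF) extraction through pluggable backends, an
    L1-penalized linear model of the modified Rodnan skin score (mRSS) with
    patient-grouped cross-validation whose patch-mean prediction is the
    biopsy-level Fibrosis Score, a 16-parameter dermatopathology scoring
    schema with Cohen's kappa rater-agreement statistics and mixed-effects
    change-per-week estimates, and ordinal-logistic association analyses
    linking histology to mRSS and Fibrosis Score. A synthetic-data module
    generates layered trichrome-like skin images, mRSS trajectories and
    paired-rater score sheets with controllable agreement so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    lme4,
    png,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
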