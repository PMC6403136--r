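Package: artcalc
Title: Mature Oocyte Number Planning for at Least One Euploid Blastocyst in
    IVF/ICSI
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clinical decision support for IVF/ICSI treatment planning built
    around a per-mature-oocyte (metaphase-II) blastocyst-euploidy probability
    model with female age and sperm source as predictors. Converts the
    per-oocyte probability into the minimum number of mature oocytes needed
    to obtain at least one euploid blastocyst at a user-chosen success
    probability (pretreatment), and revises the success probability from an
    observed oocyte count (posttreatment), propagating 95% confidence limits
    through the monotone mappings. Also provides the model-development
    pipeline the calculator derives from: aggregated-binomial logistic fits
    of per-oocyte stage outcomes, a negative-binomial count model for euploid
    blastocysts per patient, adaptive-LASSO predictor selection with
    corrected-AIC stopping, holdout ROC validation, and a calibrated
    synthetic-cohort generator for simulation testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
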