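Package: solanidine
Title: Solanidine-Based Phenotyping of CYP2D6 Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for using the dietary potato alkaloid solanidine and its
    metabolite-to-parent ratios as biomarkers of CYP2D6 enzyme activity.
    Implements CYP2D6 star-allele activity scoring and genotype-predicted
    phenotype classification (gPM/gIM/gNM/gUM, with an optional NFIB
    rs28379954 reclassification), 1/x-weighted calibration-curve
    quantification with lower-limit-of-quantification censoring rules,
    log-scale group contrasts with Fisher's least-significant-difference
    comparisons, ROC and precision-recall biomarker evaluation with
    stratified bootstrap confidence intervals and paired comparisons,
    robust-scaled tree-ensemble feature screening under repeated nested
    cross-validation, an additive-dosage association scan with linkage
    disequilibrium and conditional re-analysis, substrate-depletion
    intrinsic-clearance kinetics with well-stirred hepatic scaling, and a
    calibrated synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    xgboost
Suggests:
    pROC,
    vcfR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
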