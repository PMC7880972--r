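Package: t1liver
Title: Whole-Liver T1-Map Histogram and Texture Analysis for Fibrosis Risk Stratification
Version: 0.1.0
Authors@R:
    person("t1liver", "developers", email = "t1liver@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for stratifying the risk of advanced fibrosis
    in nonalcoholic fatty liver disease (NAFLD) from quantitative T1 maps.
    Implements variable-flip-angle (VFA) T1 fitting with B1 correction from
    spoiled gradient-echo image pairs, seeded random-walker whole-liver
    segmentation, extraction of eight histogram and four gray-level
    co-occurrence (GLCM) texture features from the masked T1 distribution,
    NFS/FIB-4 blood fibrosis scores with a two-step liver-stiffness-based risk
    stratification, and the downstream statistical chain (normality-gated
    univariate tests, stepwise logistic models, ROC with Youden cutoffs,
    DeLong AUC comparison, Hosmer-Lemeshow calibration, two-way mixed ICC).
    Ships a synthetic phantom and cohort generator so the whole chain is
    testable without patient data, plus minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
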