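Package: stentfai
Title: Peri-Stent Perivascular Fat Attenuation Index from Coronary CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measurement of the perivascular adipose tissue (PVAT) fat
    attenuation index (FAI) around coronary stents from 3D CT volumes, and
    the downstream statistical analysis of its association with in-stent
    restenosis (ISR). Includes a CT phantom simulator with known vessel,
    stent and fat ground truth, a synthetic patient-cohort generator
    calibrated to published group summaries, vessel centerline extraction
    and perpendicular cross-section resampling, lumen diameter profiling
    with the diameter-stenosis definition of ISR, peri-stent PVAT shell
    construction with Hounsfield-window attenuation averaging, and a
    statistics pipeline covering group comparisons, LASSO feature selection
    with cross-validated lambda.min/lambda.1se, adjusted logistic
    regression, ROC/AUC with DeLong intervals and Youden cutoffs, Pearson
    correlation, and two-way random-effects intraclass correlation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    pROC,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
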