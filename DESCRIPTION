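Package: pcgrade
Title: Quantitative Gleason and Cribriform-Based Grading of Prostate
    Cancer with Survival Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements three radical-prostatectomy grading systems for
    prostatic adenocarcinoma -- ISUP/WHO Grade Groups derived from Gleason
    pattern percentages, the continuous and five-tier integrated
    quantitative Gleason score (IQ-Gleason), and the cribriform grade
    (cGrade) that modifies the Grade Group for invasive cribriform and/or
    intraductal carcinoma -- together with the survival machinery used to
    compare them: Kaplan-Meier estimation, the k-group log-rank test,
    univariate Cox proportional-hazards regression by Newton-Raphson with
    Efron tie handling, Harrell's concordance index with bootstrap
    confidence intervals, sparse-group merging, and median imputation.
    A seeded synthetic-cohort generator with known ground truth emulates
    the structure of a grade-stratified prostatectomy cohort so the whole
    pipeline is testable without patient data, including an
    observer-perturbation experiment for grade-stability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
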