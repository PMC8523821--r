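Package: brainageBP
Title: Blood Pressure and Brain-Age Gap Estimation in a Longitudinal Cohort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking blood pressure to brain
    health measured as the brain-age gap (BrainAGE). Provides a synthetic
    longitudinal cohort generator (two age cohorts, up to four waves, blood
    pressure trajectories, covariates, attrition, gray-matter-like feature
    vectors with a scanner batch effect), blood-pressure derived measures and
    classification rules (mean arterial pressure, hypertension, optimal BP,
    threshold centering, outlier flagging), eligibility filtering with EM
    imputation of missing covariates, a brain-age estimation engine (Gaussian
    smoothing and resampling of volumes, scanner orthogonalization, PCA
    reduction, relevance vector regression, leave-one-subject-out estimation,
    age-bias correction), and longitudinal mixed-effects association models
    with summary-statistic group tests and reporting conversions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    RNifti
Config/testthat/edition: 3
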