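Package: planqm
Title: Plan Quality Metric Evaluation for Head-and-Neck MR-Linac Planning Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate cohorts of head-and-neck radiotherapy treatment
    plans with a tiered 150-point plan quality metric (PQM). Includes a
    voxel-phantom generator that synthesizes calibrated cohorts of dose
    distributions (three nested planning target volumes plus ten organs at
    risk), a dose-volume histogram (DVH) engine extracting D_x%, D_xcc,
    D_mean, V_xGy and the conformation number, configurable tiered scoring
    with hard-constraint and delivery-time gates, and the cohort analysis:
    relative deviations from ideal-score thresholds with exact Wilcoxon
    signed-rank tests, Spearman correlation matrices with strength
    classification, and PTV-versus-OAR trade-off fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
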