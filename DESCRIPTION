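Package: fieldprint
Title: OPLS-DA Chemometrics for Organic Food Authentication by LC-MS
    Metabolomic Fingerprinting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end chemometrics pipeline for authenticating the
    agricultural production system (organic versus conventional) of crops
    from untargeted LC-MS metabolomic fingerprints. Provides bucketing of
    centroid peak lists onto a fixed retention-time by m/z grid, per-analysis
    sum normalization, Pareto scaling with train-frozen parameters,
    principal component analysis, orthogonal projections to latent
    structures discriminant analysis (OPLS-DA) with sevenfold
    cross-validated component selection, variable importance in the
    projection (VIP) scoring and refinement, deconfounding of a dominant
    nuisance factor (such as harvest year) by removal of its VIP > 1
    variables, external validation by random-third, leave-one-year-out,
    leave-one-cultivar-out and leave-fields-out splits with sensitivity,
    specificity and ROC/AUC, S-plot marker extraction, and univariate
    marker confirmation with Bonferroni correction. Includes a synthetic
    data generator that emulates a multi-year paired-field study design
    with ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mzR,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
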