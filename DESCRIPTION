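Package: promkit
Title: Item Response Theory Evaluation Toolkit for Patient-Reported
    Outcome Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Graded response model (GRM) calibration by marginal maximum
    likelihood, expected a posteriori (EAP) scoring on the T-score metric,
    test and item information, and the full psychometric evaluation
    pipeline used for patient-reported outcome item banks: IRT assumption
    checks (polychoric correlations, single-factor fit, exploratory
    bifactor indices, Mokken scalability, monotonicity, invariant item
    ordering), generalized Orlando-Thissen S-X2 item fit, differential
    item functioning by ordinal logistic regression with McFadden pseudo
    R2 effect sizes and impact re-estimation, post-hoc computerized
    adaptive testing (CAT) simulation with maximum posterior weighted
    information selection, reliability and relative-efficiency summaries
    with bootstrap confidence intervals, construct-validity hypothesis
    ledgers, and demographically stratified reference-value tables. A
    synthetic-data module generates item banks, ceiling-skewed latent
    traits, GRM responses with injectable DIF, a correlated 0-100 legacy
    instrument, and stratified reference subsamples with known ground
    truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
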