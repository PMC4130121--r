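Package: clampval
Title: Validation of Fasting Insulin Sensitivity Indices Against the
    Euglycemic Hyperinsulinemic Clamp
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for method-comparison studies of fasting surrogate
    indices of insulin sensitivity (HOMA-IR, FIRI, QUICKI, the fasting
    glucose/insulin ratio) and clinical adiposity surrogates (BMI, waist
    circumference, waist-to-height ratio) against insulin-mediated glucose
    uptake measured by the euglycemic hyperinsulinemic clamp. Includes
    clamp M-value derivation with glucose-space correction and fat-free
    mass normalisation, Box-Cox transformation, robust correlation via EM
    estimation of a multivariate-t scatter matrix, Fisher-z confidence
    intervals, the Williams-Steiger test for dependent correlations, Huber
    M-estimator regression, sex-specific tertile concordance with Cohen's
    kappa and bootstrap confidence intervals, and a seeded synthetic-cohort
    generator for end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
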