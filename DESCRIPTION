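Package: mrkit
Title: Two-Sample and Allele-Score Mendelian Randomization for Blood
    Biomarkers and Kidney Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Summary-level and individual-level Mendelian randomization
    (MR) analysis of blood homocysteine, folate and cobalamin on kidney
    function (estimated glomerular filtration rate, eGFR). Implements
    harmonization of GWAS summary statistics with palindromic-variant
    handling, Steiger directionality filtering, and the standard
    summary-level causal estimators: fixed-effects inverse-variance
    weighted, MR-Egger with bootstrapped standard errors and intercept
    test, (penalized) weighted median, contamination mixture, and the
    single-variant Wald ratio. An individual-level replication arm
    builds weighted allele scores from a dosage matrix and fits
    covariate-adjusted linear models for eGFR computed with the CKD-EPI
    creatinine equation. Synthetic-data generators produce summary
    statistics and cohorts with the statistical structure the analysis
    assumes, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
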