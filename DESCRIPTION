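Package: dietmr
Title: One-Sample Mendelian Randomisation of Dietary Intake and Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates biobank-style cohorts (genotypes, food-frequency
    questionnaire responses, covariates and a time-to-event colorectal
    cancer outcome) and implements the full analytical chain from
    questionnaire-derived quantitative diet traits through genome-wide
    association quality control, locus selection, heritability and genetic
    correlation estimation, weighted allele-score instrument construction,
    and one-sample Mendelian randomisation with a two-stage least squares
    estimator whose second stage is an age-scale Cox proportional-hazards
    model, together with MR-Egger, MR-PRESSO and multivariable MR
    pleiotropy sensitivity analyses and the matching observational Cox
    comparison arm.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
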