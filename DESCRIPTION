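Package: mwascreen
Title: Medication-Wide Association Screening of Pregnancy Outcomes from EHR Event Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for medication-wide association studies (MWAS)
    of pregnancy outcomes in electronic health record (EHR) data. Builds a
    delivery cohort from event tables, derives cesarean section, preterm
    birth, and stillbirth outcome flags from delivery-day ICD-9/ICD-10
    diagnosis codes, constructs per-delivery binary medication exposures
    over a 280-day pre-delivery window with brand/generic merging and a
    minimum-patient inclusion filter, assembles a comorbidity adjustment
    matrix from a two-year diagnosis lookback, and screens every retained
    medication against every outcome with adjusted logistic regression,
    Wald confidence intervals, and Bonferroni family-wise control. Includes
    a configurable synthetic obstetric-EHR generator with planted effects
    and confounding so the full pipeline is testable without access to
    protected health data, a rule engine for clinical-trial candidate-drug
    exclusions, and privacy-aware table rendering with small-cell
    suppression.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
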