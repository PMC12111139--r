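Package: adhere
Title: Medication Adherence Assessment from Pharmacy Dispensing Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective adherence analysis of pharmacy
    dispensing claims, built around attention-deficit/hyperactivity
    disorder (ADHD) pharmacotherapy in adults. Implements cohort
    construction from dispensing records with an age / index-drug /
    flumazenil-only exclusion cascade and ICD-10 F90 diagnostic grouping,
    rule-based monthly medicine plotting with dispensing-month
    reassignment, treatment-adherent-group (TAG) classification,
    Proportion of Days Covered (PDC) under issue-anchored assessment-period
    segmentation, Prescribed Daily Dose (PDD) derivation with Defined
    Daily Dose comparison, and the associated inferential battery
    (exact contingency tests, TAG logistic regression with Wald and
    type-3 likelihood-ratio assessment). A seeded synthetic claims
    generator emulates five-year monthly dispensing streams so every
    stage is testable without access to proprietary medical-aid data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
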