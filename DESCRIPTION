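Package: omopetl
Title: Map Claims Data to the OMOP Common Data Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for standardizing Austrian-style health claims data into
    the OMOP Common Data Model v6.0. Classifies local vocabulary codes
    (ICD-10-BMSG diagnoses, ATC drug codes, pharmaceutical registration
    numbers, prescriber professional groups, socio-economic index) into
    mapping states S1/S2/S3 against an OMOP-style concept store, suggests
    candidate standard concepts by lexical similarity, imports mappable local
    codes as new concepts with "Maps to" relationships, runs a deterministic
    ETL from the five-table claims source into the populated CDM v6.0 subset
    (person, observation_period, provider, visit_occurrence, drug_exposure
    and the four clinical event tables), and validates the result by count
    reconciliation, record-wise equivalence and descriptive-statistic
    comparison. Includes a seeded synthetic claims-cohort and concept-store
    generator with ground truth, so the whole pipeline is testable without
    any external vocabulary download.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
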