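# omopetl

Standardize Austrian-style health claims data into the OMOP Common Data
Model (CDM) v6.0.

Social-insurance claims databases such as Austria's GAP-DRG hold
pseudonymized patients, deaths, drug prescriptions (PRN product numbers,
ATC ingredient codes, prescriber professional groups), hospital stays and
ICD-10-coded diagnoses in a proprietary relational model. Every new
pharmacoepidemiological study reprocesses the same extract from scratch,
and results are hard to compare. Mapping the data once into the OMOP CDM —
the standardized schema and terminology maintained by the OHDSI community —
makes studies reproducible and analysis tooling reusable. `omopetl`
implements that mapping as a reusable toolkit for data engineers and
pharmacoepidemiologists: vocabulary mapping, table mapping/ETL, and a
validation protocol, plus a seeded synthetic cohort generator so the whole
pipeline is testable without access to real claims or a full vocabulary
download.

## Method

**Vocabulary states.** Each local vocabulary (ICD-10-BMSG, ATC, PRN,
professional groups, socio-economic index SEI) is classified per code
against an OMOP-style concept store:

* **S1** — the code is included in the OMOP vocabularies one-to-one: it is
  present verbatim in a compatible vocabulary and resolves directly to a
  *Standard Concept* (itself, or via a single `Maps to` relationship).
* **S2** — not included one-to-one, but a semantically equivalent standard
  concept exists: either a `Concept replaced by` chain from a deprecated
  concept reaches one (vocabulary changes, e.g. a retired ATC code), or a
  manually curated hint (the USAGI-style human mapping step) supplies one.
* **S3** — no equivalent exists (e.g. the Austrian SEI); such codes carry
  concept id 0 downstream and are never imported.

S1/S2 codes are imported as new non-standard concepts (ids from the
reserved local range ≥ 2·10⁹) with exactly one `Maps to` edge each;
candidate concepts for manual S2 curation are ranked by token-set trigram
similarity between code descriptions and concept names.

**ETL.** Patients + deaths merge into `person` (CDM v6.0 keeps death as
`death_datetime`); one `observation_period` per person spans the study
period (default 2008–2011); each prescriber specialty becomes one *virtual
provider*; duplicate hospital-stay and diagnosis records are removed
(first occurrence kept); stays become inpatient `visit_occurrence` rows;
prescriptions become `drug_exposure` rows (end date = start date; PRN kept
as source value); diagnoses are split across `condition_occurrence`,
`procedure_occurrence`, `measurement` and `observation` by the domain of
their standard concept; unavailable mandatory fields (race, ethnicity,
provider gender, unmapped codes) get concept id 0. The transform is
deterministic.

**Validation.** Three checks, all exact: row-count reconciliation per
table pair (`cdm = source − duplicates removed`), record-wise equivalence
of a source-shaped view reconstructed from the CDM's source values, and
equality of descriptive indicators (percent female; lower-median age,
hospitalizations per person, prescriptions per person, length of stay)
computed identically on both sides.

## Worked example

```r
library(omopetl)

gen <- generate_source(source_gen_config(n_patients = 500, seed = 1))
fix <- generate_vocabulary_fixture(vocab_gen_config(seed = 1))
cls <- assess_source_codes(gen$dataset, fix$store, fix$hints)
cls
#> <vocab_classification> 150 codes
#>   state     n fraction
#> 1 S1       64    0.427
#> 2 S2       46    0.307
#> 3 S3       40    0.267

imp <- import_local_vocabulary(cls, fix$store)
res <- run_etl(gen$dataset, imp$store, cls, etl_config())
res$report
#> <etl_report>
#>   input rows: patient=500, death=74, prescription=10303, hospital_stay=1030, diagnosis=2543
#>   output rows:person=500, observation_period=500, provider=10, visit_occurrence=983,
#>               drug_exposure=10303, clinical_event=2435, sei_observation=450
#>   duplicates removed: stays=47, diagnoses=108

validate_etl(gen$dataset, res$cdm, res$report, etl_config())
#> <validation_report> overall: PASS
#>   count_reconciliation     pass
#>   record_equivalence       pass
#>   descriptive_statistics   pass
```

Reading the numbers: all 500 patients and all 10,303 prescriptions survive
the transform one-to-one; 47 of 1,030 stay rows and 108 of 2,543 diagnosis
rows were exact duplicates and were removed, so 983 visits and 2,435
clinical events remain — the reconciliation passes because the differences
are exactly the removed duplicates, i.e. no records were lost. Of the 150
distinct local codes, 64 matched OMOP vocabularies verbatim (S1), 46 were
resolved through replacement chains or manual hints (S2) and 40 have no
equivalent (S3, kept with concept id 0).

Descriptive indicators of the synthetic cohort (identical on the CDM
side):

```r
descriptive_stats(gen$dataset)
#>   percent_female          49.8
#>   median_age              77
#>   median_hospitalizations 2
#>   median_prescriptions    20
#>   median_length_of_stay   5
```

A command-line front end wrapping these functions is installed under
`inst/cli/omopetl` (subcommands `simulate`, `scan`, `map-vocab`, `run`,
`validate`; `validate` exits non-zero on failure, CI-friendly).

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch —
synthetic cohort generation, vocabulary classification, local-concept
import, ETL and the three-part validation — at a given seed and writes its
measurement report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

The package operates on fixture-scale concept stores and synthetic
cohorts; it does not download the Athena vocabulary release, read the real
GAP-DRG database, build study cohorts, or derive drug/condition eras. See
`vignettes/claims-to-omop.Rmd` for the methodological details and known
limitations.
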