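cfg <- etl_config()

test_that("person rows merge patients with deaths and default unknowns to 0", {
  patients <- tibble::tibble(
    patient_key = c("P1", "P2", "P3"),
    birth_year = c(1930L, 1925L, 1940L),
    sex_code = c("F", "X", NA),
    sei = c(2L, NA, 4L)
  )
  deaths <- tibble::tibble(patient_key = "P2",
                           death_date = as.Date("2010-06-01"))
  persons <- build_person(patients, deaths, cfg)
  expect_identical(persons$person_id, 1:3)
  expect_true(is.na(persons$death_datetime[1]))
  expect_identical(format(persons$death_datetime[2], "%Y-%m-%d", tz = "UTC"),
                   "2010-06-01")
  # mapped, unknown and missing sex codes
  expect_identical(persons$gender_concept_id, c(8532L, 0L, 0L))
  expect_identical(persons$gender_source_value, c("F", "X", NA))
  expect_true(all(persons$race_concept_id == 0L))
  expect_true(all(persons$ethnicity_concept_id == 0L))
  expect_error(build_person(patients[c(1, 1), ], deaths, cfg),
               "duplicate patient_key")
})

test_that("every person gets one observation period spanning the study period", {
  persons <- build_person(
    tibble::tibble(patient_key = c("P1", "P2"), birth_year = c(1930L, 1931L),
                   sex_code = "F", sei = 1L),
    tibble::tibble(patient_key = character(0), death_date = as.Date(character(0))),
    cfg
  )
  periods <- build_observation_periods(persons, cfg)
  expect_identical(nrow(periods), 2L)
  expect_true(all(periods$observation_period_start_date == as.Date("2008-01-01")))
  expect_true(all(periods$observation_period_end_date == as.Date("2011-12-31")))
})

test_that("virtual providers: one per distinct specialty, unmatched get concept 0", {
  rx <- tibble::tibble(professional_group = c("A", "B", "A"))
  assessments <- tibble::tibble(
    local_code = "A", local_vocabulary_id = "ProfessionalGroup",
    state = "S2", standard_concept_id = 42L, matched_concept_id = NA_integer_,
    evidence = "hint"
  )
  providers <- build_providers(rx, assessments)
  expect_identical(nrow(providers), 2L)
  expect_identical(providers$specialty_source_value, c("A", "B"))
  expect_identical(providers$specialty_concept_id, c(42L, 0L))
  expect_true(all(providers$gender_concept_id == 0L))
  expect_identical(nrow(build_providers(rx[0, ], assessments)), 0L)
})

test_that("deduplication keeps first occurrences and matches the oracle", {
  stay <- tibble::tibble(
    stay_key = c("S1", "S2", "S3"),
    patient_key = c("P1", "P1", "P2"),
    admission_date = as.Date(c("2008-01-01", "2008-01-01", "2008-02-01")),
    discharge_date = as.Date(c("2008-01-06", "2008-01-06", "2008-02-03"))
  )
  out <- deduplicate(stay, id_col = "stay_key")
  expect_identical(out$kept$stay_key, c("S1", "S3"))
  expect_identical(out$removed_count, 1L)
  expect_identical(out$log$removed_id, "S2")
  expect_identical(out$log$kept_id, "S1")
  # all-distinct input is untouched; idempotent
  distinct <- deduplicate(out$kept, id_col = "stay_key")
  expect_identical(distinct$removed_count, 0L)
  expect_identical(distinct$kept, out$kept)
  # generated fixtures against the exhaustive group-and-count oracle
  for (seed in c(2L, 8L)) {
    ds <- generate_source(source_gen_config(n_patients = 150L, seed = seed))$dataset
    cols <- c("patient_key", "admission_date", "discharge_date")
    dd <- deduplicate(ds$hospital_stay, cols, "stay_key")
    expect_identical(dd$removed_count, oracle_dup_count(ds$hospital_stay, cols))
  }
})

test_that("visits carry source dates and stay keys field for field", {
  run <- pipeline_run(3L, n_patients = 120L)
  visits <- run$cdm$visit_occurrence
  stays <- run$gen$dataset$hospital_stay
  # join back on the preserved stay key
  m <- match(visits$visit_source_value, stays$stay_key)
  expect_false(anyNA(m))
  expect_equal(visits$visit_start_date, stays$admission_date[m])
  expect_equal(visits$visit_end_date, stays$discharge_date[m])
  expect_true(all(visits$visit_concept_id == cfg$inpatient_visit_concept_id))
  # a stay for an unknown person is fatal
  persons <- run$cdm$person
  rogue <- stays[1, ]
  rogue$patient_key <- "UNKNOWN"
  expect_error(build_visits(rogue, persons, cfg), "unknown person")
})

test_that("drug exposures preserve PRN, map ATC and span one day", {
  run <- pipeline_run(3L, n_patients = 120L)
  drugs <- run$cdm$drug_exposure
  rx <- run$gen$dataset$prescription
  expect_identical(nrow(drugs), nrow(rx))
  expect_identical(drugs$drug_source_value, rx$prn)
  expect_equal(drugs$drug_exposure_start_date, rx$prescription_date)
  expect_equal(drugs$drug_exposure_end_date, drugs$drug_exposure_start_date)
  # mapped ATC codes carry their standard concept, unmapped carry 0
  gt <- run$fix$ground_truth
  atc_gt <- gt[gt$local_vocabulary_id == "ATC-AT", ]
  m <- match(rx$atc_code, atc_gt$local_code)
  want <- atc_gt$standard_concept_id[m]
  want[is.na(want)] <- 0L
  expect_identical(drugs$drug_concept_id, as.integer(want))
  # provider linkage carries the professional group
  pg <- run$cdm$provider$specialty_source_value[
    match(drugs$provider_id, run$cdm$provider$provider_id)]
  expect_identical(pg, rx$professional_group)
})

test_that("clinical events are partitioned across the four tables by domain", {
  run <- pipeline_run(3L, n_patients = 120L)
  cdm <- run$cdm
  sei_rows <- sum(!is.na(cdm$observation$value_as_number))
  n_events <- nrow(cdm$condition_occurrence) + nrow(cdm$procedure_occurrence) +
    nrow(cdm$measurement) + nrow(cdm$observation) - sei_rows
  expect_identical(
    n_events,
    nrow(run$gen$dataset$diagnosis) -
      as.integer(run$report$duplicates_removed[["diagnosis"]])
  )
  # routing agrees with the concept domains
  store <- run$imp$store
  check_routed <- function(df, concept_col, domain) {
    ids <- df[[concept_col]]
    ids <- ids[ids != 0L]
    if (length(ids) == 0L) return()
    dom <- store$concept$domain_id[match(ids, store$concept$concept_id)]
    expect_true(all(dom == domain))
  }
  check_routed(cdm$condition_occurrence, "condition_concept_id", "Condition")
  check_routed(cdm$procedure_occurrence, "procedure_concept_id", "Procedure")
  check_routed(cdm$measurement, "measurement_concept_id", "Measurement")
  obs <- cdm$observation[is.na(cdm$observation$value_as_number), ]
  check_routed(obs, "observation_concept_id", "Observation")
  # unmapped codes land in the default table with concept 0
  s3_icd <- run$fix$ground_truth
  s3_icd <- s3_icd$local_code[s3_icd$local_vocabulary_id == "ICD10-BMSG" &
                                s3_icd$state == "S3"]
  diag <- run$gen$dataset$diagnosis
  if (any(diag$icd10_code %in% s3_icd)) {
    unmapped <- cdm$condition_occurrence[
      cdm$condition_occurrence$condition_concept_id == 0L, ]
    expect_true(all(unmapped$condition_source_value %in% s3_icd))
    expect_gt(nrow(unmapped), 0L)
  }
})

test_that("SEI becomes one concept-0 observation per patient with an index", {
  run <- pipeline_run(3L, n_patients = 120L)
  pat <- run$gen$dataset$patient
  sei <- run$cdm$observation[!is.na(run$cdm$observation$value_as_number), ]
  expect_identical(nrow(sei), sum(!is.na(pat$sei)))
  expect_true(all(sei$observation_concept_id == 0L))
  m <- match(run$cdm$person$person_source_value[
    match(sei$person_id, run$cdm$person$person_id)], pat$patient_key)
  expect_equal(sei$value_as_number, as.numeric(pat$sei[m]))
})

test_that("run_etl conserves rows and is deterministic", {
  for (seed in c(4L, 10L)) {
    run <- pipeline_run(seed, n_patients = 150L)
    src <- run$gen$dataset
    rep <- run$report
    cdm <- run$cdm
    # conservation identities, mirroring the count comparison protocol
    expect_identical(nrow(cdm$person), length(unique(src$patient$patient_key)))
    expect_identical(nrow(cdm$drug_exposure), nrow(src$prescription))
    expect_identical(nrow(cdm$visit_occurrence) +
                       as.integer(rep$duplicates_removed[["hospital_stay"]]),
                     nrow(src$hospital_stay))
    # injected ground-truth duplicates equal the reported removals
    truth <- run$gen$ground_truth$duplicates
    expect_identical(as.integer(rep$duplicates_removed[["hospital_stay"]]),
                     sum(truth$table == "hospital_stay"))
    expect_identical(as.integer(rep$duplicates_removed[["diagnosis"]]),
                     sum(truth$table == "diagnosis"))
  }
  # two runs on identical inputs give identical outputs
  run <- pipeline_run(4L, n_patients = 150L)
  res2 <- run_etl(run$gen$dataset, run$imp$store, run$cls, cfg)
  expect_equal(res2$cdm, run$cdm)
  expect_equal(res2$report, run$report)
})

test_that("an empty source yields empty CDM tables and an all-zero report", {
  empty <- source_dataset()
  fix <- generate_vocabulary_fixture(vocab_gen_config(seed = 1L))
  res <- run_etl(empty, fix$store,
                 classify_vocabulary(tibble::tibble(code = character(0),
                                                    vocab_id = character(0)),
                                     fix$store),
                 cfg)
  for (tb in setdiff(cdm_table_names(),
                     c("concept", "concept_relationship", "vocabulary"))) {
    expect_identical(nrow(res$cdm[[tb]]), 0L)
  }
  expect_true(all(res$report$output_counts == 0L))
  expect_true(all(res$report$duplicates_removed == 0L))
})

test_that("diagnoses referencing a removed duplicate stay are re-pointed", {
  stays <- tibble::tibble(
    stay_key = c("S1", "S2"),
    patient_key = "P1",
    admission_date = as.Date("2009-03-01"),
    discharge_date = as.Date("2009-03-05")
  )
  diag <- tibble::tibble(
    diag_key = "D1", patient_key = "P1", icd10_code = "A00.1",
    stay_ref = "S2", diag_date = as.Date("2009-03-02")
  )
  src <- source_dataset(
    tibble::tibble(patient_key = "P1", birth_year = 1930L, sex_code = "F",
                   sei = NA_integer_),
    hospital_stay = stays, diagnosis = diag
  )
  res <- run_etl(src, tiny_store(),
                 classify_vocabulary(tibble::tibble(code = "A00.1",
                                                    vocab_id = "ICD10-BMSG"),
                                     tiny_store()),
                 cfg)
  # the duplicate stay S2 is removed but its diagnosis survives, linked to S1
  expect_identical(nrow(res$cdm$visit_occurrence), 1L)
  expect_identical(res$cdm$visit_occurrence$visit_source_value, "S1")
  expect_identical(nrow(res$cdm$condition_occurrence), 1L)
  expect_identical(res$cdm$condition_occurrence$visit_occurrence_id,
                   res$cdm$visit_occurrence$visit_occurrence_id)
})
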