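cfg <- etl_config()

test_that("count reconciliation passes on clean runs and flags hand damage", {
  run <- pipeline_run(5L, n_patients = 150L)
  rc <- reconcile_counts(run$gen$dataset, run$cdm, run$report)
  expect_true(all(rc$pass))
  # dedup allowance applies exactly where removals were reported
  expect_identical(rc$expected_cdm_count, rc$source_count - rc$duplicates_removed)
  truth <- run$gen$ground_truth$duplicates
  expect_identical(sum(rc$duplicates_removed), nrow(truth))
  # deleting one visit row from the CDM fails that pair with delta 1
  damaged <- run$cdm
  damaged$visit_occurrence <- damaged$visit_occurrence[-1, ]
  rc2 <- reconcile_counts(run$gen$dataset, damaged, run$report)
  row <- rc2[rc2$cdm_table == "visit_occurrence", ]
  expect_false(row$pass)
  expect_identical(row$expected_cdm_count - row$cdm_count, 1L)
  expect_true(all(rc2$pass[rc2$cdm_table != "visit_occurrence"]))
})

test_that("record-wise equivalence holds on clean runs across seeds", {
  for (seed in c(5L, 12L, 19L)) {
    run <- pipeline_run(seed, n_patients = 150L)
    diffs <- check_equivalence(run$gen$dataset, run$cdm, cfg)
    expect_identical(nrow(diffs), 0L)
  }
})

test_that("a single corrupted field yields a diff naming that field", {
  run <- pipeline_run(5L, n_patients = 150L)
  cdm <- run$cdm
  cdm$person$gender_source_value[1] <-
    if (identical(cdm$person$gender_source_value[1], "F")) "M" else "F"
  diffs <- check_equivalence(run$gen$dataset, cdm, cfg)
  expect_identical(nrow(diffs), 1L)
  expect_identical(diffs$table, "patient")
  expect_identical(diffs$field, "sex_code")
  expect_identical(diffs$row_ref, cdm$person$person_source_value[1])
})

test_that("descriptive statistics match hand arithmetic", {
  pat <- tibble::tibble(
    patient_key = c("P1", "P2", "P3", "P4"),
    birth_year = c(1930L, 1932L, 1936L, 1925L),
    sex_code = c("F", "F", "M", "M"),
    sei = c(1L, 2L, NA, 4L)
  )
  stays <- tibble::tibble(
    stay_key = c("S1", "S2", "S3"),
    patient_key = c("P1", "P1", "P2"),
    admission_date = as.Date(c("2008-01-01", "2009-01-01", "2010-01-01")),
    discharge_date = as.Date(c("2008-01-04", "2009-01-06", "2010-01-08"))
  )
  ds <- source_dataset(pat, hospital_stay = stays)
  st <- descriptive_stats(ds)
  expect_equal(st$percent_female, 50)
  # ages at 2008: 78, 76, 72, 83 -> lower median 76
  expect_equal(st$median_age, 76)
  # stays per person with >=1: {2, 1} -> lower median 1; including zeros: {2,1,0,0} -> 0
  expect_equal(st$median_hospitalizations, 1)
  expect_equal(st$median_hospitalizations_incl_zero, 0)
  # stay lengths {3, 5, 7} -> median 5
  expect_equal(st$median_length_of_stay, 5)
  expect_true(is.na(st$median_prescriptions))
  # empty person table -> indicators undefined, not zero
  empty <- descriptive_stats(source_dataset())
  expect_true(is.na(empty$percent_female))
  expect_true(is.na(empty$median_age))
})

test_that("lower-median convention returns observed values", {
  expect_equal(lower_median(c(3, 5, 7)), 5)
  expect_equal(lower_median(c(2, 4, 6, 8)), 4)
  expect_equal(lower_median(c(NA, 9)), 9)
  expect_true(is.na(lower_median(numeric(0))))
})

test_that("indicators agree with a straight-line recomputation and between sides", {
  for (seed in c(6L, 13L)) {
    run <- pipeline_run(seed, n_patients = 150L)
    src_stats <- descriptive_stats(run$gen$dataset, cfg$study_start, cfg)
    want <- oracle_stats(run$gen$dataset)
    for (nm in names(want)) expect_equal(src_stats[[nm]], want[[nm]], info = nm)
    cdm_stats <- descriptive_stats(run$cdm, cfg$study_start, cfg)
    cmp <- compare_stats(src_stats, cdm_stats)
    expect_true(all(cmp$equal))
  }
})

test_that("validate_etl aggregates the three checks into one verdict", {
  run <- pipeline_run(5L, n_patients = 150L)
  vr <- validate_etl(run$gen$dataset, run$cdm, run$report, cfg)
  expect_true(vr$passed)
  expect_true(all(vr$component_pass))
  # corruptions that touch exactly one check flip exactly that check
  flip_one <- list(
    prn = function(cdm) {
      cdm$drug_exposure$drug_source_value[1] <- "CORRUPT"
      cdm
    },
    stay_key = function(cdm) {
      cdm$visit_occurrence$visit_source_value[1] <- "CORRUPT"
      cdm
    },
    sei = function(cdm) {
      i <- which(!is.na(cdm$person$sei_source_value))[1]
      cdm$person$sei_source_value[i] <- "99"
      cdm
    }
  )
  for (nm in names(flip_one)) {
    vr2 <- validate_etl(run$gen$dataset, flip_one[[nm]](run$cdm), run$report, cfg)
    expect_false(vr2$passed, info = nm)
    expect_identical(unname(vr2$component_pass),
                     c(TRUE, FALSE, TRUE), info = nm)
  }
})

test_that("validation reports round-trip through JSON", {
  run <- pipeline_run(5L, n_patients = 150L)
  vr <- validate_etl(run$gen$dataset, run$cdm, run$report, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_validation_report(vr, path)
  back <- read_validation_report(path)
  expect_equal(back$counts, vr$counts)
  expect_equal(back$diffs, vr$diffs)
  expect_equal(back$stats, vr$stats)
  expect_identical(back$component_pass, vr$component_pass)
  expect_identical(back$passed, vr$passed)
  # a failing report survives the round trip too
  cdm <- run$cdm
  cdm$drug_exposure$drug_source_value[1] <- "CORRUPT"
  vr2 <- validate_etl(run$gen$dataset, cdm, run$report, cfg)
  write_validation_report(vr2, path)
  back2 <- read_validation_report(path)
  expect_equal(back2$diffs, vr2$diffs)
  expect_false(back2$passed)
})

test_that("ETL reports round-trip through JSON", {
  run <- pipeline_run(5L, n_patients = 150L)
  path <- withr::local_tempfile(fileext = ".json")
  write_etl_report(run$report, path)
  back <- read_etl_report(path)
  expect_equal(back$input_counts, run$report$input_counts)
  expect_equal(back$output_counts, run$report$output_counts)
  expect_equal(back$duplicates_removed, run$report$duplicates_removed)
  expect_equal(back$dedup_log, run$report$dedup_log)
})
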