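# Validation of an ETL run: count reconciliation per table pair,
# record-wise equivalence between the CDM and the (deduplicated) source,
# and comparison of descriptive statistics computed on both sides.

.recon_pairs <- tibble::tibble(
  source_table = c("patient", "prescription", "hospital_stay", "diagnosis"),
  cdm_table = c("person", "drug_exposure", "visit_occurrence", "clinical_event")
)

#' Reconcile row counts between source and CDM
#'
#' Compares the row counts of corresponding table pairs: patients against
#' person, prescriptions against drug_exposure, hospital stays against
#' visit_occurrence, diagnoses against the union of the four clinical event
#' tables (SEI observations excluded). The deduplication allowance is
#' applied only where the ETL report claims removals: a pair passes iff
#' `cdm = source - removed`.
#'
#' @param source the [source_dataset()] the run consumed.
#' @param cdm the produced [cdm_dataset()].
#' @param etl_report the `etl_report` from the same [run_etl()] call.
#' @return A `count_reconciliation` tibble: one row per table pair with
#'   `source_count`, `duplicates_removed`, `expected_cdm_count`,
#'   `cdm_count` and `pass`.
#' @export
reconcile_counts <- function(source, cdm, etl_report) {
  stopifnot(inherits(source, "source_dataset"), inherits(cdm, "cdm_dataset"),
            inherits(etl_report, "etl_report"))
  sei_rows <- sum(!is.na(cdm$observation$value_as_number))
  cdm_counts <- c(
    person = nrow(cdm$person),
    drug_exposure = nrow(cdm$drug_exposure),
    visit_occurrence = nrow(cdm$visit_occurrence),
    clinical_event = nrow(cdm$condition_occurrence) +
      nrow(cdm$procedure_occurrence) + nrow(cdm$measurement) +
      (nrow(cdm$observation) - sei_rows)
  )
  removed <- c(person = 0L, drug_exposure = 0L,
               visit_occurrence = unname(etl_report$duplicates_removed[["hospital_stay"]]),
               clinical_event = unname(etl_report$duplicates_removed[["diagnosis"]]))
  out <- .recon_pairs
  out$source_count <- vapply(out$source_table, function(tb) nrow(source[[tb]]),
                             integer(1), USE.NAMES = FALSE)
  out$duplicates_removed <- as.integer(removed[out$cdm_table])
  out$expected_cdm_count <- out$source_count - out$duplicates_removed
  out$cdm_count <- as.integer(cdm_counts[out$cdm_table])
  out$pass <- out$cdm_count == out$expected_cdm_count
  class(out) <- c("count_reconciliation", class(out))
  out
}

# ---- source view reconstruction ------------------------------------------

#' Reconstruct a source-shaped view from a CDM dataset
#'
#' Inverts the ETL using the preserved source values and source concepts:
#' person rows back to patients (and deaths, from `death_datetime`),
#' drug_exposure rows back to prescriptions (ATC recovered through the
#' imported local concept in `drug_source_concept_id`; unrecoverable when
#' that is 0), visit_occurrence back to hospital stays (via the stay key in
#' `visit_source_value`), and the four clinical event tables back to
#' diagnoses (SEI observation rows, recognizable by a non-missing
#' `value_as_number`, are excluded). This is the CDM side of record-wise
#' equivalence checking and of the descriptive-statistic comparison.
#'
#' @param cdm a [cdm_dataset()].
#' @return Named list of tibbles shaped like the source tables (`diag_key`
#'   and per-row keys are not recovered; prescriptions carry an `atc_code`
#'   of `NA` where unrecoverable).
#' @export
cdm_source_view <- function(cdm) {
  stopifnot(inherits(cdm, "cdm_dataset"))
  pe <- cdm$person
  patient <- tibble::tibble(
    patient_key = pe$person_source_value,
    birth_year = pe$year_of_birth,
    sex_code = pe$gender_source_value,
    sei = as.integer(pe$sei_source_value)
  )
  died <- !is.na(pe$death_datetime)
  death <- tibble::tibble(
    patient_key = pe$person_source_value[died],
    death_date = as.Date(format(pe$death_datetime[died], "%Y-%m-%d", tz = "UTC"))
  )
  de <- cdm$drug_exposure
  pm <- function(ids) pe$person_source_value[match(ids, pe$person_id)]
  atc <- cdm$concept$concept_code[match(de$drug_source_concept_id,
                                        cdm$concept$concept_id)]
  prescription <- tibble::tibble(
    patient_key = pm(de$person_id),
    prescription_date = de$drug_exposure_start_date,
    prn = de$drug_source_value,
    atc_code = atc,
    professional_group = cdm$provider$specialty_source_value[
      match(de$provider_id, cdm$provider$provider_id)]
  )
  vo <- cdm$visit_occurrence
  hospital_stay <- tibble::tibble(
    stay_key = vo$visit_source_value,
    patient_key = pm(vo$person_id),
    admission_date = vo$visit_start_date,
    discharge_date = vo$visit_end_date
  )
  stay_of <- function(vids) vo$visit_source_value[match(vids, vo$visit_occurrence_id)]
  event_part <- function(df, date_col, src_col) {
    tibble::tibble(
      patient_key = pm(df$person_id),
      icd10_code = df[[src_col]],
      stay_ref = stay_of(df$visit_occurrence_id),
      diag_date = df[[date_col]]
    )
  }
  ob <- cdm$observation[is.na(cdm$observation$value_as_number), , drop = FALSE]
  diagnosis <- dplyr::bind_rows(
    event_part(cdm$condition_occurrence, "condition_start_date", "condition_source_value"),
    event_part(cdm$procedure_occurrence, "procedure_date", "procedure_source_value"),
    event_part(cdm$measurement, "measurement_date", "measurement_source_value"),
    event_part(ob, "observation_date", "observation_source_value")
  )
  list(patient = patient, death = death, prescription = prescription,
       hospital_stay = hospital_stay, diagnosis = diagnosis)
}

.diff_row <- function(table, row_ref, field, source_value, cdm_value) {
  tibble::tibble(table = table, row_ref = as.character(row_ref),
                 field = field,
                 source_value = as.character(source_value),
                 cdm_value = as.character(cdm_value))
}

.empty_diffs <- function() .diff_row(character(0), character(0), character(0),
                                     character(0), character(0))

# Field-for-field comparison of two tables joined on an id column.
.diff_by_id <- function(table, src, cdmv, id_col, fields) {
  diffs <- list(.empty_diffs())
  only_src <- setdiff(src[[id_col]], cdmv[[id_col]])
  if (length(only_src) > 0L) {
    diffs <- c(diffs, list(.diff_row(table, only_src, "<row>", "present", "absent")))
  }
  only_cdm <- setdiff(cdmv[[id_col]], src[[id_col]])
  if (length(only_cdm) > 0L) {
    diffs <- c(diffs, list(.diff_row(table, only_cdm, "<row>", "absent", "present")))
  }
  common <- intersect(src[[id_col]], cdmv[[id_col]])
  s <- src[match(common, src[[id_col]]), , drop = FALSE]
  cc <- cdmv[match(common, cdmv[[id_col]]), , drop = FALSE]
  for (f in fields) {
    a <- s[[f]]
    b <- cc[[f]]
    ne <- which(xor(is.na(a), is.na(b)) | (!is.na(a) & !is.na(b) & a != b))
    if (length(ne) > 0L) {
      diffs <- c(diffs, list(.diff_row(table, common[ne], f, a[ne], b[ne])))
    }
  }
  dplyr::bind_rows(diffs)
}

# Multiset comparison on a full-field tuple for tables without a recovered
# row identity (prescriptions, diagnoses).
.diff_by_tuple <- function(table, src, cdmv, cols) {
  ks <- tuple_key(src, cols)
  kc <- tuple_key(cdmv, cols)
  ts <- table(ks)
  tc <- table(kc)
  all_keys <- union(names(ts), names(tc))
  ns <- ifelse(all_keys %in% names(ts), as.integer(ts[all_keys]), 0L)
  nc <- ifelse(all_keys %in% names(tc), as.integer(tc[all_keys]), 0L)
  bad <- which(ns != nc)
  if (length(bad) == 0L) return(.empty_diffs())
  .diff_row(table, gsub("\r", "|", all_keys[bad]), "<multiplicity>",
            ns[bad], nc[bad])
}

#' Record-wise equivalence between source and CDM
#'
#' Reconstructs a source-shaped view from the CDM ([cdm_source_view()]) and
#' compares it field-for-field against the deduplicated source. Patients,
#' deaths and hospital stays are matched on their keys; prescriptions and
#' diagnoses, which carry no recoverable row key, are compared as multisets
#' of their full field tuples (the deduplicated tuples are unique for
#' diagnoses). The ATC code of a prescription is compared only where
#' recoverable through the imported source concept. A clean ETL run yields
#' an empty diff list; any discrepancy is returned, never fatal.
#'
#' @param source the [source_dataset()] consumed by the run.
#' @param cdm the produced [cdm_dataset()].
#' @param config the [etl_config()] of the run (for the dedup key).
#' @return Tibble of differences: `table`, `row_ref`, `field`,
#'   `source_value`, `cdm_value`. Zero rows means equivalence.
#' @export
check_equivalence <- function(source, cdm, config = etl_config()) {
  stopifnot(inherits(source, "source_dataset"), inherits(cdm, "cdm_dataset"))
  view <- cdm_source_view(cdm)
  keys <- .dedup_keys(config)
  stays <- deduplicate(source$hospital_stay, keys$hospital_stay, "stay_key")
  diagnosis <- source$diagnosis
  if (nrow(stays$log) > 0L) {
    remap <- match(diagnosis$stay_ref, stays$log$removed_id)
    hit <- !is.na(remap)
    diagnosis$stay_ref[hit] <- stays$log$kept_id[remap[hit]]
  }
  diags <- deduplicate(diagnosis, keys$diagnosis, "diag_key")

  pat_src <- source$patient
  diffs <- list(
    .diff_by_id("patient", pat_src, view$patient, "patient_key",
                c("birth_year", "sex_code", "sei")),
    .diff_by_id("death", source$death, view$death, "patient_key", "death_date"),
    .diff_by_id("hospital_stay", stays$kept, view$hospital_stay, "stay_key",
                c("patient_key", "admission_date", "discharge_date"))
  )
  rx_src <- source$prescription
  rx_cdm <- view$prescription
  # ATC is recoverable only for imported (S1/S2) codes; restrict the
  # compared tuple accordingly, per row, by blanking unrecoverable ATCs on
  # the source side too.
  recoverable <- !is.na(rx_cdm$atc_code)
  if (any(!recoverable)) {
    known_atc <- unique(rx_cdm$atc_code[recoverable])
    rx_src <- rx_src
    rx_src$atc_code[!rx_src$atc_code %in% known_atc] <- NA_character_
  }
  diffs <- c(diffs, list(
    .diff_by_tuple("prescription", rx_src, rx_cdm,
                   c("patient_key", "prescription_date", "prn", "atc_code",
                     "professional_group")),
    .diff_by_tuple("diagnosis", diags$kept, view$diagnosis,
                   c("patient_key", "icd10_code", "stay_ref", "diag_date"))
  ))
  dplyr::bind_rows(diffs)
}

# ---- descriptive statistics ----------------------------------------------

#' Descriptive statistical indicators of a claims cohort
#'
#' Computes the five indicators used to demonstrate ETL success: percent
#' female, median age at the reference date, median number of
#' hospitalizations per person (among persons with at least one stay),
#' median number of prescriptions per person (among persons with at least
#' one prescription), and median length of stay in days (discharge minus
#' admission; same-day stays count 0). Medians use the lower-median
#' convention ([lower_median()]), so integer inputs give integer medians.
#' Duplicate hospital-stay and diagnosis records are removed before
#' computing, on both the source and the CDM side, so a clean ETL run gives
#' exactly equal indicators. The zero-inclusive medians are additionally
#' reported as `median_hospitalizations_incl_zero` and
#' `median_prescriptions_incl_zero`.
#'
#' @param x a [source_dataset()], a [cdm_dataset()] (converted through
#'   [cdm_source_view()]), or a plain source-shaped list of tibbles.
#' @param reference_date date at which age is computed; defaults to the
#'   study period start of the default [etl_config()].
#' @param config an [etl_config()] supplying the dedup key.
#' @return A named list of class `descriptive_stats`. Indicators on an
#'   empty person table are `NA` (undefined), not zero.
#' @export
descriptive_stats <- function(x, reference_date = etl_config()$study_start,
                              config = etl_config()) {
  tabs <- if (inherits(x, "cdm_dataset")) {
    cdm_source_view(x)
  } else if (inherits(x, "source_dataset") || is.list(x)) {
    x
  } else {
    stop_omopetl("unsupported input for descriptive_stats")
  }
  reference_date <- as_date_strict(reference_date, what = "reference_date")
  keys <- .dedup_keys(config)
  stays <- deduplicate(tibble::as_tibble(tabs$hospital_stay),
                       keys$hospital_stay, "stay_key")$kept
  dg <- tibble::as_tibble(tabs$diagnosis)
  pat <- tibble::as_tibble(tabs$patient)
  rx <- tibble::as_tibble(tabs$prescription)
  n <- nrow(pat)
  if (n == 0L) {
    out <- list(n_persons = 0L, percent_female = NA_real_, median_age = NA_real_,
                median_hospitalizations = NA_real_,
                median_hospitalizations_incl_zero = NA_real_,
                median_prescriptions = NA_real_,
                median_prescriptions_incl_zero = NA_real_,
                median_length_of_stay = NA_real_)
    return(structure(out, class = "descriptive_stats"))
  }
  per_person <- function(keys_with_record) {
    counts <- table(keys_with_record)
    with_zero <- as.integer(counts[match(pat$patient_key, names(counts))])
    with_zero[is.na(with_zero)] <- 0L
    with_zero
  }
  hosp <- per_person(stays$patient_key)
  rxn <- per_person(rx$patient_key)
  los <- as.numeric(stays$discharge_date - stays$admission_date)
  ref_year <- as.integer(format(reference_date, "%Y"))
  structure(list(
    n_persons = n,
    percent_female = 100 * sum(pat$sex_code == "F", na.rm = TRUE) / n,
    median_age = lower_median(ref_year - pat$birth_year),
    median_hospitalizations = lower_median(hosp[hosp > 0L]),
    median_hospitalizations_incl_zero = lower_median(hosp),
    median_prescriptions = lower_median(rxn[rxn > 0L]),
    median_prescriptions_incl_zero = lower_median(rxn),
    median_length_of_stay = lower_median(los)
  ), class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat("<descriptive_stats>\n")
  for (nm in names(x)) cat(sprintf("  %-36s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

.stats_indicators <- c("percent_female", "median_age",
                       "median_hospitalizations", "median_prescriptions",
                       "median_length_of_stay")

#' Compare descriptive statistics of source and CDM
#'
#' @param source_stats,cdm_stats `descriptive_stats` of the two sides,
#'   computed with identical conventions.
#' @return Tibble with `indicator`, `source_value`, `cdm_value`, `equal`
#'   (exact equality; `NA` indicators compare equal only to `NA`).
#' @export
compare_stats <- function(source_stats, cdm_stats) {
  sv <- unname(unlist(source_stats[.stats_indicators]))
  cv <- unname(unlist(cdm_stats[.stats_indicators]))
  tibble::tibble(
    indicator = .stats_indicators,
    source_value = as.numeric(sv),
    cdm_value = as.numeric(cv),
    equal = (is.na(sv) & is.na(cv)) | (!is.na(sv) & !is.na(cv) & sv == cv)
  )
}

#' Validate an ETL run
#'
#' Aggregates the three validation components: count reconciliation
#' ([reconcile_counts()]), record-wise equivalence ([check_equivalence()])
#' and descriptive-statistic comparison ([descriptive_stats()] on both
#' sides). The overall verdict passes iff every component passes.
#'
#' @param source the consumed [source_dataset()].
#' @param cdm the produced [cdm_dataset()].
#' @param etl_report the `etl_report` of the same run.
#' @param config the run's [etl_config()].
#' @return A `validation_report`: list with `counts`, `diffs`, `stats`,
#'   per-component pass flags in `component_pass`, and `passed`.
#' @export
validate_etl <- function(source, cdm, etl_report, config = etl_config()) {
  counts <- reconcile_counts(source, cdm, etl_report)
  diffs <- check_equivalence(source, cdm, config)
  stats <- compare_stats(
    descriptive_stats(source, config$study_start, config),
    descriptive_stats(cdm, config$study_start, config)
  )
  component_pass <- c(
    count_reconciliation = all(counts$pass),
    record_equivalence = nrow(diffs) == 0L,
    descriptive_statistics = all(stats$equal)
  )
  structure(
    list(counts = counts, diffs = diffs, stats = stats,
         component_pass = component_pass, passed = all(component_pass)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> overall:", if (x$passed) "PASS" else "FAIL", "\n")
  for (nm in names(x$component_pass)) {
    cat(sprintf("  %-24s %s\n", nm, if (x$component_pass[[nm]]) "pass" else "FAIL"))
  }
  if (!x$component_pass[["count_reconciliation"]]) print(x$counts)
  if (nrow(x$diffs) > 0L) {
    cat("  first differing records:\n")
    print(utils::head(x$diffs, 5L))
  }
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report a `validation_report`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(
    list(
      counts = as.data.frame(report$counts),
      diffs = as.data.frame(report$diffs),
      stats = as.data.frame(report$stats),
      component_pass = as.list(report$component_pass),
      passed = report$passed
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Read a validation report written by [write_validation_report()]
#'
#' @param path JSON file.
#' @return A `validation_report` equal to the one written.
#' @export
read_validation_report <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  counts <- tibble::as_tibble(raw$counts)
  for (cl in c("source_count", "duplicates_removed", "expected_cdm_count",
               "cdm_count")) {
    counts[[cl]] <- as.integer(counts[[cl]])
  }
  counts$pass <- as.logical(counts$pass)
  class(counts) <- c("count_reconciliation", class(counts))
  diffs <- if (length(raw$diffs) == 0L) .empty_diffs() else {
    d <- tibble::as_tibble(raw$diffs)
    for (cl in names(d)) d[[cl]] <- as.character(d[[cl]])
    d
  }
  stats <- tibble::as_tibble(raw$stats)
  stats$source_value <- as.numeric(stats$source_value)
  stats$cdm_value <- as.numeric(stats$cdm_value)
  stats$equal <- as.logical(stats$equal)
  structure(
    list(counts = counts, diffs = diffs, stats = stats,
         component_pass = unlist(raw$component_pass), passed = raw$passed),
    class = "validation_report"
  )
}
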