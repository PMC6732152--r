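# ETL: transform a claims source dataset into the OMOP CDM v6.0 subset.
#
# Stage order: stage -> deduplicate stays -> deduplicate diagnoses ->
# persons -> observation periods -> providers -> visits -> drug exposures ->
# clinical events -> SEI observations. The whole transform is deterministic:
# identical inputs give identical outputs. Patients and deaths merge into
# person (death as death_datetime); one observation period per person spans
# the study period; prescribers become one virtual provider per specialty;
# duplicate hospital-stay and diagnosis records are removed; diagnoses are
# split across condition_occurrence / procedure_occurrence / measurement /
# observation by the domain of their standard concept.

#' ETL configuration
#'
#' @param study_start,study_end study period bounds; every person's
#'   observation period spans exactly this interval (default 2008--2011).
#' @param default_event_table event table receiving diagnoses whose code has
#'   no standard concept (concept id 0).
#' @param inpatient_visit_concept_id concept id recorded on every hospital
#'   stay visit.
#' @param gender_map named integer vector from source sex codes to gender
#'   concept ids; codes outside the map (or missing) become concept 0.
#' @param dedup_key `"full_row"` removes records identical on every field
#'   except the synthetic row key (the default, minimal faithful reading of
#'   duplicate removal); `"business_key"` restricts the key to person, dates
#'   and code.
#' @param sei_concept_id observation concept id for the socio-economic
#'   index; 0 because SEI has no OMOP equivalent (state S3).
#' @return An `etl_config`.
#' @export
etl_config <- function(study_start = "2008-01-01", study_end = "2011-12-31",
                       default_event_table = "condition_occurrence",
                       inpatient_visit_concept_id = 9201L,
                       gender_map = c("F" = 8532L, "M" = 8507L),
                       dedup_key = c("full_row", "business_key"),
                       sei_concept_id = 0L) {
  study_start <- as_date_strict(study_start, what = "study_start")
  study_end <- as_date_strict(study_end, what = "study_end")
  if (study_start > study_end) stop_omopetl("study_start after study_end")
  stopifnot(default_event_table %in% .event_tables)
  structure(
    list(study_start = study_start, study_end = study_end,
         default_event_table = default_event_table,
         inpatient_visit_concept_id = as.integer(inpatient_visit_concept_id),
         gender_map = gender_map,
         dedup_key = match.arg(dedup_key),
         sei_concept_id = as.integer(sei_concept_id)),
    class = "etl_config"
  )
}

# Per-(vocab, code) lookup of resolved standard concept ids; NA -> 0.
.standard_for <- function(assessments, vocab, codes) {
  rows <- match(paste(vocab, codes, sep = "\r"),
                paste(assessments$local_vocabulary_id, assessments$local_code,
                      sep = "\r"))
  out <- assessments$standard_concept_id[rows]
  out[is.na(out)] <- 0L
  as.integer(out)
}

# Imported local concept id for (vocab, code) in the store; 0 if absent.
.source_concept_for <- function(store, vocab, codes) {
  rows <- match(paste(vocab, codes, sep = "\r"),
                paste(store$concept$vocabulary_id, store$concept$concept_code,
                      sep = "\r"))
  out <- store$concept$concept_id[rows]
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Stage a source dataset
#'
#' Copies the source tables into a staging area keyed for join-back; every
#' source row is present exactly once, before any deduplication.
#'
#' @param source a [source_dataset()].
#' @return A `staging_area` (named list of tibbles).
#' @export
stage_source <- function(source) {
  stopifnot(inherits(source, "source_dataset"))
  structure(
    list(patient = source$patient, death = source$death,
         prescription = source$prescription,
         hospital_stay = source$hospital_stay,
         diagnosis = source$diagnosis),
    class = "staging_area"
  )
}

#' Remove duplicate records
#'
#' Keeps the first occurrence of every distinct key tuple, in stable input
#' order. The default key is the full field tuple excluding the synthetic
#' row identity. Idempotent: re-applying changes nothing.
#'
#' @param records tibble of staged records.
#' @param key_cols columns forming the duplicate key; defaults to all
#'   columns except `id_col`.
#' @param id_col name of the synthetic row-identity column (excluded from
#'   the key and used to label the removal log); `NULL` uses row numbers.
#' @return List: `kept` (tibble), `removed_count`, and `log` — one row per
#'   removed record with `removed_id` and the `kept_id` of the retained
#'   representative.
#' @export
deduplicate <- function(records, key_cols = NULL, id_col = NULL) {
  records <- tibble::as_tibble(records)
  key_cols <- key_cols %||% setdiff(names(records), id_col)
  key <- tuple_key(records, key_cols)
  first <- match(key, key)
  dup <- first != seq_along(key)
  ids <- if (is.null(id_col)) as.character(seq_len(nrow(records))) else records[[id_col]]
  list(
    kept = records[!dup, , drop = FALSE],
    removed_count = sum(dup),
    log = tibble::tibble(removed_id = ids[dup], kept_id = ids[first[dup]])
  )
}

#' Build the person table
#'
#' Merges patients and deaths into one person row per patient (CDM v6.0:
#' death is `death_datetime` on person, at midnight). Sex codes are mapped
#' through the configured gender map; unknown or missing codes get concept
#' 0 with the source value preserved. Race and ethnicity are unavailable in
#' claims, so their concept ids are 0.
#'
#' @param patients,deaths staged source tables.
#' @param config an [etl_config()].
#' @return Tibble of person rows, ids sequential in source order.
#' @export
build_person <- function(patients, deaths, config) {
  if (anyDuplicated(patients$patient_key)) {
    stop_omopetl("duplicate patient_key: ",
                 paste(unique(patients$patient_key[duplicated(patients$patient_key)]),
                       collapse = ", "))
  }
  gender <- unname(config$gender_map[patients$sex_code])
  gender[is.na(gender)] <- 0L
  death_date <- deaths$death_date[match(patients$patient_key, deaths$patient_key)]
  tibble::tibble(
    person_id = seq_len(nrow(patients)),
    gender_concept_id = as.integer(gender),
    year_of_birth = patients$birth_year,
    death_datetime = as.POSIXct(format(death_date), tz = "UTC"),
    race_concept_id = 0L,
    ethnicity_concept_id = 0L,
    person_source_value = patients$patient_key,
    gender_source_value = patients$sex_code,
    sei_source_value = ifelse(is.na(patients$sei), NA_character_,
                              as.character(patients$sei))
  )
}

#' Build observation periods
#'
#' No enrolment interval exists in the source, so every person gets exactly
#' one observation period spanning the whole study period, regardless of
#' their event dates.
#'
#' @param persons person table from [build_person()].
#' @param config an [etl_config()].
#' @return Tibble of observation_period rows.
#' @export
build_observation_periods <- function(persons, config) {
  tibble::tibble(
    observation_period_id = seq_len(nrow(persons)),
    person_id = persons$person_id,
    observation_period_start_date = rep(config$study_start, nrow(persons)),
    observation_period_end_date = rep(config$study_end, nrow(persons))
  )
}

#' Build virtual providers
#'
#' The source carries only the prescriber's professional group, while a CDM
#' provider may have a single specialty; so each distinct professional
#' group becomes one virtual provider. Groups without a mapped specialty
#' concept (state S3, e.g. "other facility") get concept 0 with the source
#' value preserved. Provider gender is unavailable: concept 0.
#'
#' @param prescriptions staged prescription table.
#' @param assessments assessment tibble covering vocabulary
#'   `"ProfessionalGroup"`.
#' @return Tibble of provider rows, ids assigned in sorted specialty order.
#' @export
build_providers <- function(prescriptions, assessments) {
  groups <- sort(unique(prescriptions$professional_group))
  groups <- groups[!is.na(groups)]
  tibble::tibble(
    provider_id = seq_along(groups),
    specialty_concept_id = .standard_for(assessments, "ProfessionalGroup", groups),
    specialty_source_value = groups,
    gender_concept_id = rep(0L, length(groups))
  )
}

#' Build visit occurrences from deduplicated hospital stays
#'
#' One inpatient visit per kept stay; the source `stay_key` is preserved in
#' `visit_source_value` for record-wise validation.
#'
#' @param stays deduplicated hospital-stay tibble.
#' @param persons person table.
#' @param config an [etl_config()].
#' @return Tibble of visit_occurrence rows.
#' @export
build_visits <- function(stays, persons, config) {
  pid <- persons$person_id[match(stays$patient_key, persons$person_source_value)]
  if (anyNA(pid)) {
    stop_omopetl("hospital stay for unknown person: ",
                 paste(unique(stays$patient_key[is.na(pid)]), collapse = ", "))
  }
  tibble::tibble(
    visit_occurrence_id = seq_len(nrow(stays)),
    person_id = pid,
    visit_concept_id = rep(config$inpatient_visit_concept_id, nrow(stays)),
    visit_start_date = stays$admission_date,
    visit_end_date = stays$discharge_date,
    visit_source_value = stays$stay_key
  )
}

#' Build drug exposures
#'
#' One exposure per prescription (prescriptions are never deduplicated).
#' `drug_concept_id` is the standard concept of the ATC code (0 when
#' unmapped); the PRN is kept as `drug_source_value` and the imported local
#' ATC concept as `drug_source_concept_id`. The exposure end date is not in
#' the source and is set equal to the start date — the least-information
#' choice satisfying end >= start. The prescriber's professional group
#' links to its virtual provider.
#'
#' @param prescriptions staged prescription table.
#' @param assessments assessments covering vocabulary `"ATC-AT"`.
#' @param providers provider table from [build_providers()].
#' @param persons person table.
#' @param store concept store after local import (resolves source concepts).
#' @return Tibble of drug_exposure rows.
#' @export
build_drug_exposures <- function(prescriptions, assessments, providers,
                                 persons, store) {
  pid <- persons$person_id[match(prescriptions$patient_key,
                                 persons$person_source_value)]
  if (anyNA(pid)) {
    stop_omopetl("prescription for unknown person: ",
                 paste(unique(prescriptions$patient_key[is.na(pid)]), collapse = ", "))
  }
  tibble::tibble(
    drug_exposure_id = seq_len(nrow(prescriptions)),
    person_id = pid,
    drug_concept_id = .standard_for(assessments, "ATC-AT", prescriptions$atc_code),
    drug_exposure_start_date = prescriptions$prescription_date,
    drug_exposure_end_date = prescriptions$prescription_date,
    drug_source_value = prescriptions$prn,
    drug_source_concept_id = .source_concept_for(store, "ATC-AT",
                                                 prescriptions$atc_code),
    provider_id = providers$provider_id[match(prescriptions$professional_group,
                                              providers$specialty_source_value)]
  )
}

#' Build clinical event rows from deduplicated diagnoses
#'
#' Routes each kept diagnosis to condition_occurrence,
#' procedure_occurrence, measurement or observation by the domain of its
#' standard concept ([route_domain()]); unmapped codes go to the configured
#' default table with concept 0. The event date is the diagnosis date when
#' present, else the linked stay's admission date. The ICD-10 source code
#' is preserved in the table's source_value; stay linkage is preserved via
#' `visit_occurrence_id`.
#'
#' @param diagnoses deduplicated diagnosis tibble.
#' @param assessments assessments covering vocabulary `"ICD10-BMSG"`.
#' @param store concept store after local import.
#' @param visits visit table from [build_visits()].
#' @param persons person table.
#' @param config an [etl_config()].
#' @return Named list of the four event tibbles.
#' @export
build_clinical_events <- function(diagnoses, assessments, store, visits,
                                  persons, config) {
  pid <- persons$person_id[match(diagnoses$patient_key,
                                 persons$person_source_value)]
  if (anyNA(pid)) {
    stop_omopetl("diagnosis for unknown person: ",
                 paste(unique(diagnoses$patient_key[is.na(pid)]), collapse = ", "))
  }
  visit_row <- match(diagnoses$stay_ref, visits$visit_source_value)
  if (any(!is.na(diagnoses$stay_ref) & is.na(visit_row))) {
    stop_omopetl("diagnosis stay_ref does not resolve to a visit: ",
                 paste(unique(diagnoses$stay_ref[!is.na(diagnoses$stay_ref) &
                                                   is.na(visit_row)]), collapse = ", "))
  }
  concept <- .standard_for(assessments, "ICD10-BMSG", diagnoses$icd10_code)
  event_date <- diagnoses$diag_date
  use_stay <- is.na(event_date) & !is.na(visit_row)
  event_date[use_stay] <- visits$visit_start_date[visit_row[use_stay]]
  if (anyNA(event_date)) {
    stop_omopetl("diagnosis without date or resolvable stay: ",
                 paste(diagnoses$diag_key[is.na(event_date)], collapse = ", "))
  }
  target <- route_domain(concept, store, config$default_event_table)
  base <- tibble::tibble(
    person_id = pid,
    concept_id = concept,
    event_date = event_date,
    visit_occurrence_id = visits$visit_occurrence_id[visit_row],
    source_value = diagnoses$icd10_code,
    source_concept_id = .source_concept_for(store, "ICD10-BMSG",
                                            diagnoses$icd10_code),
    target = target
  )
  shape <- function(df, id_col, cc, dc, sv, sc) {
    out <- tibble::tibble(
      id = seq_len(nrow(df)),
      person_id = df$person_id, concept = df$concept_id,
      date = df$event_date, visit = df$visit_occurrence_id,
      src = df$source_value, src_c = df$source_concept_id
    )
    names(out) <- c(id_col, "person_id", cc, dc, "visit_occurrence_id", sv, sc)
    out
  }
  events <- list(
    condition_occurrence = shape(base[base$target == "condition_occurrence", ],
                                 "condition_occurrence_id", "condition_concept_id",
                                 "condition_start_date", "condition_source_value",
                                 "condition_source_concept_id"),
    procedure_occurrence = shape(base[base$target == "procedure_occurrence", ],
                                 "procedure_occurrence_id", "procedure_concept_id",
                                 "procedure_date", "procedure_source_value",
                                 "procedure_source_concept_id"),
    measurement = shape(base[base$target == "measurement", ],
                        "measurement_id", "measurement_concept_id",
                        "measurement_date", "measurement_source_value",
                        "measurement_source_concept_id")
  )
  obs <- base[base$target == "observation", ]
  events$observation <- tibble::tibble(
    observation_id = seq_len(nrow(obs)),
    person_id = obs$person_id,
    observation_concept_id = obs$concept_id,
    observation_date = obs$event_date,
    value_as_number = rep(NA_real_, nrow(obs)),
    visit_occurrence_id = obs$visit_occurrence_id,
    observation_source_value = obs$source_value,
    observation_source_concept_id = obs$source_concept_id
  )
  events
}

#' Build SEI observations
#'
#' The Austrian socio-economic index has no OMOP equivalent (state S3), so
#' each patient with an SEI gets one observation row with concept id 0, the
#' numeric index in `value_as_number`, dated at the study period start (the
#' source records no date for it).
#'
#' @param patients staged patient table.
#' @param persons person table.
#' @param config an [etl_config()].
#' @return Tibble of observation rows (ids start at 1; renumbered when
#'   appended by [run_etl()]).
#' @export
build_sei_observations <- function(patients, persons, config) {
  has_sei <- !is.na(patients$sei)
  p <- patients[has_sei, , drop = FALSE]
  tibble::tibble(
    observation_id = seq_len(nrow(p)),
    person_id = persons$person_id[match(p$patient_key, persons$person_source_value)],
    observation_concept_id = rep(config$sei_concept_id, nrow(p)),
    observation_date = rep(config$study_start, nrow(p)),
    value_as_number = as.numeric(p$sei),
    visit_occurrence_id = rep(NA_integer_, nrow(p)),
    observation_source_value = as.character(p$sei),
    observation_source_concept_id = rep(0L, nrow(p))
  )
}

.dedup_keys <- function(config) {
  if (config$dedup_key == "full_row") {
    list(hospital_stay = c("patient_key", "admission_date", "discharge_date"),
         diagnosis = c("patient_key", "icd10_code", "stay_ref", "diag_date"))
  } else {
    list(hospital_stay = c("patient_key", "admission_date", "discharge_date"),
         diagnosis = c("patient_key", "icd10_code", "diag_date"))
  }
}

#' Run the full ETL
#'
#' Orchestrates the transform end-to-end: stage, deduplicate hospital stays
#' and diagnoses (remapping diagnosis stay references from removed
#' duplicates to their kept representative), then build persons,
#' observation periods, providers, visits, drug exposures, clinical events
#' and SEI observations. The run is deterministic and all-or-nothing:
#' errors propagate before any output object is produced.
#'
#' @param source a [source_dataset()].
#' @param store the [concept_store()] after [import_local_vocabulary()].
#' @param assessments assessment tibble (or `vocab_classification`)
#'   covering the source's ICD-10, ATC and professional-group codes.
#' @param config an [etl_config()].
#' @return List: `cdm` (a validated [cdm_dataset()]) and `report` (an
#'   `etl_report`: input/output row counts per table, duplicates removed,
#'   unmapped-code and defaulted-field tallies).
#' @export
run_etl <- function(source, store, assessments, config = etl_config()) {
  stopifnot(inherits(source, "source_dataset"), inherits(store, "concept_store"),
            inherits(config, "etl_config"))
  if (inherits(assessments, "vocab_classification")) {
    assessments <- assessments$assessments
  }
  staged <- stage_source(source)
  keys <- .dedup_keys(config)

  stay_dedup <- deduplicate(staged$hospital_stay, keys$hospital_stay, "stay_key")
  diagnosis <- staged$diagnosis
  if (nrow(stay_dedup$log) > 0L) {
    # re-point stay references of removed duplicates at the kept stay
    remap <- match(diagnosis$stay_ref, stay_dedup$log$removed_id)
    hit <- !is.na(remap)
    diagnosis$stay_ref[hit] <- stay_dedup$log$kept_id[remap[hit]]
  }
  diag_dedup <- deduplicate(diagnosis, keys$diagnosis, "diag_key")

  persons <- build_person(staged$patient, staged$death, config)
  periods <- build_observation_periods(persons, config)
  providers <- build_providers(staged$prescription, assessments)
  visits <- build_visits(stay_dedup$kept, persons, config)
  drugs <- build_drug_exposures(staged$prescription, assessments, providers,
                                persons, store)
  events <- build_clinical_events(diag_dedup$kept, assessments, store, visits,
                                  persons, config)
  sei <- build_sei_observations(staged$patient, persons, config)
  observation <- dplyr::bind_rows(events$observation, sei)
  observation$observation_id <- seq_len(nrow(observation))

  cdm <- cdm_dataset(
    person = persons, observation_period = periods, provider = providers,
    visit_occurrence = visits, drug_exposure = drugs,
    condition_occurrence = events$condition_occurrence,
    procedure_occurrence = events$procedure_occurrence,
    measurement = events$measurement, observation = observation,
    store = store
  )

  n_events <- nrow(events$condition_occurrence) + nrow(events$procedure_occurrence) +
    nrow(events$measurement) + nrow(events$observation)
  report <- structure(list(
    input_counts = vapply(staged, nrow, integer(1)),
    output_counts = c(
      person = nrow(persons), observation_period = nrow(periods),
      provider = nrow(providers), visit_occurrence = nrow(visits),
      drug_exposure = nrow(drugs), clinical_event = n_events,
      sei_observation = nrow(sei)
    ),
    duplicates_removed = c(hospital_stay = stay_dedup$removed_count,
                           diagnosis = diag_dedup$removed_count),
    dedup_log = list(hospital_stay = stay_dedup$log, diagnosis = diag_dedup$log),
    unmapped = c(
      atc_prescriptions = sum(drugs$drug_concept_id == 0L),
      icd_diagnoses = sum(c(events$condition_occurrence$condition_concept_id,
                            events$procedure_occurrence$procedure_concept_id,
                            events$measurement$measurement_concept_id,
                            events$observation$observation_concept_id) == 0L),
      specialties = sum(providers$specialty_concept_id == 0L)
    ),
    defaulted = c(
      gender_concept_zero = sum(persons$gender_concept_id == 0L),
      race_ethnicity_zero = nrow(persons),
      drug_end_date_set = nrow(drugs),
      provider_gender_zero = nrow(providers)
    )
  ), class = "etl_report")

  list(cdm = cdm, report = report)
}

#' @export
print.etl_report <- function(x, ...) {
  cat("<etl_report>\n  input rows: ",
      paste(names(x$input_counts), x$input_counts, sep = "=", collapse = ", "),
      "\n  output rows:",
      paste(names(x$output_counts), x$output_counts, sep = "=", collapse = ", "),
      "\n  duplicates removed: stays=", x$duplicates_removed[["hospital_stay"]],
      ", diagnoses=", x$duplicates_removed[["diagnosis"]], "\n", sep = "")
  invisible(x)
}

#' Write an ETL report as JSON
#'
#' @param report an `etl_report` from [run_etl()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_etl_report <- function(report, path) {
  stopifnot(inherits(report, "etl_report"))
  jsonlite::write_json(
    list(
      input_counts = as.list(report$input_counts),
      output_counts = as.list(report$output_counts),
      duplicates_removed = as.list(report$duplicates_removed),
      dedup_log = report$dedup_log,
      unmapped = as.list(report$unmapped),
      defaulted = as.list(report$defaulted)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an ETL report written by [write_etl_report()]
#'
#' @param path JSON file.
#' @return An `etl_report` equal to the one written.
#' @export
read_etl_report <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  as_log <- function(x) {
    if (length(x) == 0L) {
      tibble::tibble(removed_id = character(0), kept_id = character(0))
    } else {
      tibble::tibble(removed_id = as.character(x$removed_id),
                     kept_id = as.character(x$kept_id))
    }
  }
  structure(list(
    input_counts = unlist(raw$input_counts),
    output_counts = unlist(raw$output_counts),
    duplicates_removed = unlist(raw$duplicates_removed),
    dedup_log = list(hospital_stay = as_log(raw$dedup_log$hospital_stay),
                     diagnosis = as_log(raw$dedup_log$diagnosis)),
    unmapped = unlist(raw$unmapped),
    defaulted = unlist(raw$defaulted)
  ), class = "etl_report")
}
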