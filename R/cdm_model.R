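# OMOP CDM v6.0 subset: the tables this pipeline populates, their schema,
# domain routing, and CSV persistence. v6.0 carries death on the person row
# (death_datetime), so there is no separate death table. Unpopulated columns
# outside this subset are out of scope; tables in the subset that receive no
# rows are still emitted, empty.

.cdm_col_types <- list(
  person = c(person_id = "integer", gender_concept_id = "integer",
             year_of_birth = "integer", death_datetime = "datetime",
             race_concept_id = "integer", ethnicity_concept_id = "integer",
             person_source_value = "character", gender_source_value = "character",
             sei_source_value = "character"),
  observation_period = c(observation_period_id = "integer", person_id = "integer",
                         observation_period_start_date = "date",
                         observation_period_end_date = "date"),
  provider = c(provider_id = "integer", specialty_concept_id = "integer",
               specialty_source_value = "character", gender_concept_id = "integer"),
  visit_occurrence = c(visit_occurrence_id = "integer", person_id = "integer",
                       visit_concept_id = "integer", visit_start_date = "date",
                       visit_end_date = "date", visit_source_value = "character"),
  drug_exposure = c(drug_exposure_id = "integer", person_id = "integer",
                    drug_concept_id = "integer",
                    drug_exposure_start_date = "date",
                    drug_exposure_end_date = "date",
                    drug_source_value = "character",
                    drug_source_concept_id = "integer", provider_id = "integer"),
  condition_occurrence = c(condition_occurrence_id = "integer", person_id = "integer",
                           condition_concept_id = "integer",
                           condition_start_date = "date",
                           visit_occurrence_id = "integer",
                           condition_source_value = "character",
                           condition_source_concept_id = "integer"),
  procedure_occurrence = c(procedure_occurrence_id = "integer", person_id = "integer",
                           procedure_concept_id = "integer",
                           procedure_date = "date",
                           visit_occurrence_id = "integer",
                           procedure_source_value = "character",
                           procedure_source_concept_id = "integer"),
  measurement = c(measurement_id = "integer", person_id = "integer",
                  measurement_concept_id = "integer", measurement_date = "date",
                  visit_occurrence_id = "integer",
                  measurement_source_value = "character",
                  measurement_source_concept_id = "integer"),
  observation = c(observation_id = "integer", person_id = "integer",
                  observation_concept_id = "integer", observation_date = "date",
                  value_as_number = "numeric", visit_occurrence_id = "integer",
                  observation_source_value = "character",
                  observation_source_concept_id = "integer"),
  concept = c(concept_id = "integer", concept_name = "character",
              domain_id = "character", vocabulary_id = "character",
              concept_code = "character", is_standard = "logical"),
  concept_relationship = c(concept_id_1 = "integer", concept_id_2 = "integer",
                           relationship_id = "character"),
  vocabulary = c(vocabulary_id = "character", vocabulary_name = "character",
                 vocabulary_version = "character")
)

# Clinical event tables a diagnosis may be routed to, by concept domain.
.event_tables <- c(Condition = "condition_occurrence",
                   Procedure = "procedure_occurrence",
                   Measurement = "measurement",
                   Observation = "observation")

#' CDM table names of the populated subset
#'
#' @return Character vector of the table names emitted by [write_cdm()],
#'   clinical tables first, vocabulary tables last.
#' @export
cdm_table_names <- function() names(.cdm_col_types)

.empty_cdm_table <- function(table) {
  spec <- .cdm_col_types[[table]]
  cols <- lapply(spec, function(tp) {
    switch(tp,
      integer = integer(0), character = character(0), numeric = numeric(0),
      logical = logical(0), date = as.Date(character(0)),
      datetime = as.POSIXct(character(0), tz = "UTC")
    )
  })
  tibble::as_tibble(cols)
}

.coerce_cdm_table <- function(df, table) {
  spec <- .cdm_col_types[[table]]
  df <- tibble::as_tibble(df)
  missing <- setdiff(names(spec), names(df))
  if (length(missing) > 0L) {
    stop_omopetl("cdm table '", table, "' is missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  df <- df[names(spec)]
  for (cl in names(spec)) {
    df[[cl]] <- switch(spec[[cl]],
      integer = as.integer(df[[cl]]),
      character = as.character(df[[cl]]),
      numeric = as.numeric(df[[cl]]),
      logical = as.logical(df[[cl]]),
      date = as_date_strict(df[[cl]], what = paste0(table, ".", cl)),
      datetime = if (inherits(df[[cl]], "POSIXct")) {
        v <- df[[cl]]
        attr(v, "tzone") <- "UTC"
        v
      } else {
        v <- as.character(df[[cl]])
        v[!is.na(v) & v == ""] <- NA_character_
        as.POSIXct(v, tz = "UTC")
      }
    )
  }
  df
}

#' Assemble an OMOP CDM dataset
#'
#' Bundles the populated CDM v6.0 subset tables (person,
#' observation_period, provider, visit_occurrence, drug_exposure, the four
#' clinical event tables) together with the vocabulary tables of the
#' concept store used for the run. All tables are coerced to the declared
#' schema and referential integrity is verified.
#'
#' @param ... named data frames, one per CDM table; omitted tables default
#'   to empty. Alternatively pass `store = <concept_store>` to fill the
#'   three vocabulary tables at once.
#' @param validate run [validate_cdm_dataset()] (default TRUE).
#' @return A `cdm_dataset`: named list of tibbles.
#' @export
cdm_dataset <- function(..., validate = TRUE) {
  args <- list(...)
  if (!is.null(args$store)) {
    st <- args$store
    stopifnot(inherits(st, "concept_store"))
    args$concept <- st$concept
    args$concept_relationship <- st$concept_relationship
    args$vocabulary <- st$vocabulary
    args$store <- NULL
  }
  unknown <- setdiff(names(args), cdm_table_names())
  if (length(unknown) > 0L) {
    stop_omopetl("unknown cdm table(s): ", paste(unknown, collapse = ", "))
  }
  tables <- lapply(cdm_table_names(), function(tb) {
    if (is.null(args[[tb]])) .empty_cdm_table(tb)
    else .coerce_cdm_table(args[[tb]], tb)
  })
  names(tables) <- cdm_table_names()
  cdm <- structure(tables, class = "cdm_dataset")
  if (validate) validate_cdm_dataset(cdm) else cdm
}

#' Validate a CDM dataset
#'
#' Verifies primary-key uniqueness, that every foreign key
#' (`person_id`, `visit_occurrence_id`, `provider_id`) resolves, that each
#' person has at most one observation period, that date intervals are
#' ordered, and that every concept-id-valued field is either 0 or resolves
#' in the bundled concept table. Violations are fatal and list offenders.
#'
#' @param cdm a `cdm_dataset`.
#' @return `cdm`, for chaining.
#' @export
validate_cdm_dataset <- function(cdm) {
  stopifnot(inherits(cdm, "cdm_dataset"))
  fail <- function(...) stop_omopetl(...)
  for (tb in cdm_table_names()) {
    idcol <- names(.cdm_col_types[[tb]])[[1L]]
    if (endsWith(idcol, "_id") && anyDuplicated(cdm[[tb]][[idcol]])) {
      fail("duplicate ", idcol, " in ", tb)
    }
  }
  persons <- cdm$person$person_id
  concept_ids <- cdm$concept$concept_id
  check_fk <- function(tb, col, universe, what) {
    v <- cdm[[tb]][[col]]
    bad <- setdiff(v[!is.na(v)], universe)
    if (length(bad) > 0L) {
      fail("dangling ", what, " in ", tb, ".", col, ": ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  for (tb in c("observation_period", "visit_occurrence", "drug_exposure",
               unname(.event_tables))) {
    check_fk(tb, "person_id", persons, "person_id")
  }
  for (tb in unname(.event_tables)) {
    check_fk(tb, "visit_occurrence_id", cdm$visit_occurrence$visit_occurrence_id,
             "visit_occurrence_id")
  }
  check_fk("drug_exposure", "provider_id", cdm$provider$provider_id, "provider_id")
  concept_cols <- list(
    person = c("gender_concept_id", "race_concept_id", "ethnicity_concept_id"),
    provider = c("specialty_concept_id", "gender_concept_id"),
    visit_occurrence = "visit_concept_id",
    drug_exposure = c("drug_concept_id", "drug_source_concept_id"),
    condition_occurrence = c("condition_concept_id", "condition_source_concept_id"),
    procedure_occurrence = c("procedure_concept_id", "procedure_source_concept_id"),
    measurement = c("measurement_concept_id", "measurement_source_concept_id"),
    observation = c("observation_concept_id", "observation_source_concept_id")
  )
  for (tb in names(concept_cols)) {
    for (cl in concept_cols[[tb]]) {
      v <- cdm[[tb]][[cl]]
      bad <- setdiff(v[!is.na(v) & v != 0L], concept_ids)
      if (length(bad) > 0L) {
        fail("concept id does not resolve in ", tb, ".", cl, ": ",
             paste(utils::head(bad, 5L), collapse = ", "))
      }
    }
  }
  if (anyDuplicated(cdm$observation_period$person_id)) {
    fail("more than one observation period for a person")
  }
  op <- cdm$observation_period
  if (any(op$observation_period_start_date > op$observation_period_end_date)) {
    fail("observation period start after end")
  }
  vo <- cdm$visit_occurrence
  if (any(vo$visit_start_date > vo$visit_end_date)) {
    fail("visit start after end")
  }
  de <- cdm$drug_exposure
  if (any(de$drug_exposure_start_date > de$drug_exposure_end_date)) {
    fail("drug exposure start after end")
  }
  if (anyDuplicated(cdm$provider$specialty_source_value)) {
    fail("more than one provider per specialty_source_value")
  }
  cdm
}

#' @export
print.cdm_dataset <- function(x, ...) {
  cat("<cdm_dataset> (OMOP CDM v6.0 subset)\n")
  for (tb in cdm_table_names()) {
    cat(sprintf("  %-22s %7d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

#' Route a standard concept to its clinical event table
#'
#' OMOP routes clinical facts by the domain of their standard concept:
#' Condition to condition_occurrence, Procedure to procedure_occurrence,
#' Measurement to measurement, Observation to observation. The zero concept
#' (unmapped) goes to the configurable default table. Any other domain is
#' an error here.
#'
#' @param standard_concept_id integer vector of standard concept ids (0 for
#'   unmapped).
#' @param store a [concept_store()] resolving the ids.
#' @param default_table event table used for the zero concept.
#' @return Character vector of target table names, same length as input.
#' @export
route_domain <- function(standard_concept_id, store,
                         default_table = "condition_occurrence") {
  stopifnot(default_table %in% .event_tables)
  ids <- as.integer(standard_concept_id)
  out <- rep(NA_character_, length(ids))
  out[ids == 0L] <- default_table
  nonzero <- which(ids != 0L)
  if (length(nonzero) > 0L) {
    rows <- match(ids[nonzero], store$concept$concept_id)
    if (anyNA(rows)) {
      stop_omopetl("concept id not in store: ",
                   paste(unique(ids[nonzero][is.na(rows)]), collapse = ", "))
    }
    domains <- store$concept$domain_id[rows]
    tabs <- .event_tables[domains]
    if (anyNA(tabs)) {
      bad <- unique(domains[is.na(tabs)])
      stop_omopetl("unroutable domain for clinical events: ",
                   paste(bad, collapse = ", "))
    }
    out[nonzero] <- unname(tabs)
  }
  out
}

# ---- persistence ----------------------------------------------------------

#' Write a CDM dataset as one CSV per table
#'
#' Emits every table of the populated subset (lower-case OMOP table and
#' column names), including empty ones — an unpopulated table is written
#' with its header only, never omitted. Dates are ISO-8601; death_datetime
#' is written as `YYYY-MM-DD HH:MM:SS` UTC. The dataset is validated before
#' anything is written, so a failed run leaves no partial sink.
#'
#' @param cdm a `cdm_dataset`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cdm <- function(cdm, dir) {
  validate_cdm_dataset(cdm)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in cdm_table_names()) {
    df <- cdm[[tb]]
    spec <- .cdm_col_types[[tb]]
    for (cl in names(spec)) {
      if (spec[[cl]] == "datetime") {
        df[[cl]] <- format(df[[cl]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
      }
    }
    readr::write_csv(df, file.path(dir, paste0(tb, ".csv")), na = "",
                     progress = FALSE)
  }
  invisible(dir)
}

#' Read a CDM dataset written by [write_cdm()]
#'
#' @param dir directory holding one CSV per CDM table.
#' @param validate verify integrity after reading (default TRUE).
#' @return A `cdm_dataset` equal to the one written.
#' @export
read_cdm <- function(dir, validate = TRUE) {
  tables <- lapply(cdm_table_names(), function(tb) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) stop_omopetl("cdm table file not found: ", path)
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    na = "", progress = FALSE, show_col_types = FALSE)
  })
  names(tables) <- cdm_table_names()
  do.call(cdm_dataset, c(tables, list(validate = validate)))
}

#' SQL DDL for the populated CDM subset
#'
#' Reference schema of the emitted tables as `CREATE TABLE` statements
#' (integer ids, `date`/`timestamp` temporals, `varchar` source values).
#'
#' @return A single character string of SQL DDL.
#' @export
cdm_ddl <- function() {
  sql_type <- c(integer = "integer", character = "varchar(255)",
                numeric = "numeric", logical = "boolean",
                date = "date", datetime = "timestamp")
  stmts <- vapply(cdm_table_names(), function(tb) {
    spec <- .cdm_col_types[[tb]]
    cols <- paste0("  ", names(spec), " ", sql_type[unname(spec)],
                   collapse = ",\n")
    paste0("CREATE TABLE ", tb, " (\n", cols, "\n);")
  }, character(1))
  paste(stmts, collapse = "\n\n")
}
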