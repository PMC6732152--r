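# Claims-source data model: five flat tables (patients, deaths,
# prescriptions, hospital stays, diagnoses), CSV IO and a WhiteRabbit-style
# scan report of tables, columns, types and value frequencies.

.source_tables <- c("patient", "death", "prescription", "hospital_stay", "diagnosis")

.source_schema <- list(
  patient       = c(patient_key = "character", birth_year = "integer",
                    sex_code = "character", sei = "integer"),
  death         = c(patient_key = "character", death_date = "date"),
  prescription  = c(patient_key = "character", prescription_date = "date",
                    prn = "character", atc_code = "character",
                    professional_group = "character"),
  hospital_stay = c(stay_key = "character", patient_key = "character",
                    admission_date = "date", discharge_date = "date"),
  diagnosis     = c(diag_key = "character", patient_key = "character",
                    icd10_code = "character", stay_ref = "character",
                    diag_date = "date")
)

# Row-identity columns that may be absent in raw files; assigned in file order.
.source_auto_keys <- c(hospital_stay = "stay_key", diagnosis = "diag_key")

#' CSV dialect for claims source files
#'
#' Describes how the five source CSV files are encoded. Canonical files are
#' comma-separated UTF-8 with ISO-8601 (`YYYY-MM-DD`) dates; an alternate
#' input date format may be declared for reading legacy extracts. Written
#' files are always canonical.
#'
#' @param delimiter field separator, default `","`.
#' @param encoding file encoding, default `"UTF-8"`.
#' @param date_format `strptime` format used to parse date columns on input.
#' @return An object of class `source_dialect`.
#' @export
source_dialect <- function(delimiter = ",", encoding = "UTF-8",
                           date_format = "%Y-%m-%d") {
  stopifnot(is.character(delimiter), nchar(delimiter) == 1L)
  structure(
    list(delimiter = delimiter, encoding = encoding, date_format = date_format),
    class = "source_dialect"
  )
}

.empty_source_table <- function(table) {
  spec <- .source_schema[[table]]
  cols <- lapply(spec, function(tp) {
    switch(tp,
      character = character(0),
      integer   = integer(0),
      date      = as.Date(character(0))
    )
  })
  tibble::as_tibble(cols)
}

.coerce_source_table <- function(df, table, date_format = "%Y-%m-%d") {
  spec <- .source_schema[[table]]
  df <- tibble::as_tibble(df)
  auto <- .source_auto_keys[table]
  if (!is.na(auto) && !auto %in% names(df)) {
    # assign stable sequential keys in file order
    prefix <- toupper(substr(table, 1L, 1L))
    df[[auto]] <- if (nrow(df)) sprintf("%s%07d", prefix, seq_len(nrow(df))) else character(0)
  }
  missing <- setdiff(names(spec), names(df))
  if (length(missing) > 0L) {
    stop_omopetl("table '", table, "' is missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), names(spec))
  if (length(extra) > 0L) {
    stop_omopetl("table '", table, "' has unknown column(s): ",
                 paste(extra, collapse = ", "))
  }
  df <- df[names(spec)]
  for (cl in names(spec)) {
    df[[cl]] <- switch(spec[[cl]],
      character = {
        v <- as.character(df[[cl]])
        v[!is.na(v) & v == ""] <- NA_character_
        v
      },
      integer = as.integer(df[[cl]]),
      date = as_date_strict(df[[cl]], format = date_format,
                            what = paste0(table, ".", cl))
    )
  }
  df
}

#' Assemble a claims source dataset
#'
#' Bundles the five source tables into a validated `source_dataset`. Columns
#' are coerced to the declared schema; missing `stay_key`/`diag_key` row
#' identities are assigned sequentially in row order. All referential and
#' structural invariants are checked (see [validate_source_dataset()]).
#'
#' @param patient,death,prescription,hospital_stay,diagnosis data frames
#'   matching the source schema; defaults are empty tables.
#' @param dialect a [source_dialect()].
#' @param birth_year_range plausible range for `birth_year`.
#' @return A `source_dataset`: a named list of five tibbles plus dialect
#'   metadata.
#' @export
source_dataset <- function(patient = NULL, death = NULL, prescription = NULL,
                           hospital_stay = NULL, diagnosis = NULL,
                           dialect = source_dialect(),
                           birth_year_range = c(1880L, 2030L)) {
  tables <- list(patient = patient, death = death, prescription = prescription,
                 hospital_stay = hospital_stay, diagnosis = diagnosis)
  tables <- lapply(.source_tables, function(tb) {
    if (is.null(tables[[tb]])) .empty_source_table(tb)
    else .coerce_source_table(tables[[tb]], tb, dialect$date_format)
  })
  names(tables) <- .source_tables
  ds <- structure(
    c(tables, list(dialect = dialect, birth_year_range = as.integer(birth_year_range))),
    class = "source_dataset"
  )
  validate_source_dataset(ds)
}

#' Validate a claims source dataset
#'
#' Checks the structural invariants of the source model: unique patient keys,
#' plausible birth years, at most one death per patient, referential
#' integrity of every `patient_key` and `stay_ref`, non-empty ATC and ICD-10
#' codes, and `admission_date <= discharge_date`. Violations are fatal and
#' name the offending keys.
#'
#' @param ds a `source_dataset`.
#' @return `ds`, invisibly usable in a pipe (returned visibly for chaining).
#' @export
validate_source_dataset <- function(ds) {
  stopifnot(inherits(ds, "source_dataset"))
  pat <- ds$patient
  dup <- pat$patient_key[duplicated(pat$patient_key)]
  if (length(dup) > 0L) {
    stop_omopetl("duplicate patient_key: ", paste(unique(dup), collapse = ", "))
  }
  byr <- pat$birth_year
  bad <- pat$patient_key[!is.na(byr) &
                           (byr < ds$birth_year_range[1L] | byr > ds$birth_year_range[2L])]
  if (length(bad) > 0L) {
    stop_omopetl("implausible birth_year for patient(s): ",
                 paste(bad, collapse = ", "))
  }
  check_ref <- function(keys, table) {
    unknown <- setdiff(keys[!is.na(keys)], pat$patient_key)
    if (length(unknown) > 0L) {
      stop_omopetl("table '", table, "' references unknown patient_key: ",
                   paste(unknown, collapse = ", "))
    }
  }
  check_ref(ds$death$patient_key, "death")
  check_ref(ds$prescription$patient_key, "prescription")
  check_ref(ds$hospital_stay$patient_key, "hospital_stay")
  check_ref(ds$diagnosis$patient_key, "diagnosis")
  dupd <- ds$death$patient_key[duplicated(ds$death$patient_key)]
  if (length(dupd) > 0L) {
    stop_omopetl("more than one death row for patient(s): ",
                 paste(unique(dupd), collapse = ", "))
  }
  if (any(is.na(ds$prescription$atc_code))) {
    stop_omopetl("prescription rows with empty atc_code")
  }
  hs <- ds$hospital_stay
  if (anyDuplicated(hs$stay_key)) {
    stop_omopetl("duplicate stay_key in hospital_stay")
  }
  badstay <- hs$stay_key[!is.na(hs$admission_date) & !is.na(hs$discharge_date) &
                           hs$admission_date > hs$discharge_date]
  if (length(badstay) > 0L) {
    stop_omopetl("admission_date after discharge_date for stay(s): ",
                 paste(badstay, collapse = ", "))
  }
  dg <- ds$diagnosis
  if (anyDuplicated(dg$diag_key)) {
    stop_omopetl("duplicate diag_key in diagnosis")
  }
  if (any(is.na(dg$icd10_code))) {
    stop_omopetl("diagnosis rows with empty icd10_code")
  }
  dangling <- setdiff(dg$stay_ref[!is.na(dg$stay_ref)], hs$stay_key)
  if (length(dangling) > 0L) {
    stop_omopetl("diagnosis stay_ref does not resolve: ",
                 paste(dangling, collapse = ", "))
  }
  ds
}

#' @export
print.source_dataset <- function(x, ...) {
  cat("<source_dataset>\n")
  for (tb in .source_tables) {
    cat(sprintf("  %-14s %6d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}

.source_paths <- function(dir) {
  stats::setNames(file.path(dir, paste0(.source_tables, ".csv")), .source_tables)
}

#' Read a claims source dataset from CSV files
#'
#' Reads the five source tables (`patient.csv`, `death.csv`,
#' `prescription.csv`, `hospital_stay.csv`, `diagnosis.csv`) and returns a
#' validated [source_dataset()]. Missing files, header mismatches,
#' unparseable dates and referential violations are fatal. Row identities
#' absent in the files are assigned sequentially in file order, stably
#' across re-reads.
#'
#' @param paths a directory containing the five canonical file names, or a
#'   named character vector/list with one path per table.
#' @param dialect a [source_dialect()] describing the input files.
#' @return A `source_dataset`.
#' @export
read_source <- function(paths, dialect = source_dialect()) {
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths[[1L]])) {
    paths <- .source_paths(paths[[1L]])
  }
  paths <- unlist(paths)
  missing_tb <- setdiff(.source_tables, names(paths))
  if (length(missing_tb) > 0L) {
    stop_omopetl("no path given for table(s): ", paste(missing_tb, collapse = ", "))
  }
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0L) {
    stop_omopetl("source file(s) not found: ", paste(absent, collapse = ", "))
  }
  raw <- lapply(.source_tables, function(tb) {
    df <- readr::read_delim(
      paths[[tb]], delim = dialect$delimiter,
      col_types = readr::cols(.default = readr::col_character()),
      locale = readr::locale(encoding = dialect$encoding),
      na = character(0), progress = FALSE, show_col_types = FALSE
    )
    expected <- names(.source_schema[[tb]])
    optional <- .source_auto_keys[tb]
    required <- setdiff(expected, optional[!is.na(optional)])
    if (!all(required %in% names(df)) || !all(names(df) %in% expected)) {
      stop_omopetl("header of ", paths[[tb]], " does not match the '", tb,
                   "' schema (expected: ", paste(expected, collapse = ", "), ")")
    }
    df
  })
  names(raw) <- .source_tables
  source_dataset(raw$patient, raw$death, raw$prescription, raw$hospital_stay,
                 raw$diagnosis, dialect = dialect)
}

#' Write a claims source dataset to canonical CSV files
#'
#' Writes the five tables as comma-separated UTF-8 files with ISO-8601 dates
#' into `dir` using the canonical file names. [read_source()] on the output
#' reproduces the dataset field-for-field.
#'
#' @param ds a `source_dataset`.
#' @param dir output directory, created if needed.
#' @return The directory path, invisibly.
#' @export
write_source <- function(ds, dir) {
  stopifnot(inherits(ds, "source_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- .source_paths(dir)
  for (tb in .source_tables) {
    readr::write_csv(ds[[tb]], paths[[tb]], na = "", progress = FALSE)
  }
  invisible(dir)
}

#' Scan a source dataset (WhiteRabbit-style profile)
#'
#' Produces a report of every table and column: row count, declared type,
#' fraction of missing values and the top-k most frequent values. This is
#' the local-data scan that mapping rules are designed against.
#'
#' @param ds a `source_dataset`.
#' @param top_k number of most-frequent values to keep per column.
#' @return A `scan_report`: a list with one entry per table, each holding
#'   `row_count` and a per-column list of `type`, `fraction_missing` and a
#'   `value`/`count` frequency table. Serializable with
#'   [write_scan_report()].
#' @export
profile_source <- function(ds, top_k = 20L) {
  stopifnot(inherits(ds, "source_dataset"), top_k >= 1L)
  tables <- lapply(.source_tables, function(tb) {
    df <- ds[[tb]]
    spec <- .source_schema[[tb]]
    cols <- lapply(names(spec), function(cl) {
      v <- df[[cl]]
      n <- length(v)
      freq <- if (n == 0L) {
        tibble::tibble(value = character(0), count = integer(0))
      } else {
        tab <- table(as.character(v[!is.na(v)]))
        tab <- sort(tab, decreasing = TRUE)
        tab <- tab[seq_len(min(length(tab), top_k))]
        tibble::tibble(value = names(tab), count = as.integer(tab))
      }
      list(
        name = cl,
        type = unname(spec[[cl]]),
        fraction_missing = if (n == 0L) 0 else mean(is.na(v)),
        frequencies = freq
      )
    })
    names(cols) <- names(spec)
    list(name = tb, row_count = nrow(df), columns = cols)
  })
  names(tables) <- .source_tables
  structure(list(tables = tables, top_k = as.integer(top_k)),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat("<scan_report>\n")
  for (tb in x$tables) {
    cat(sprintf("  %-14s %6d rows, %d columns\n",
                tb$name, tb$row_count, length(tb$columns)))
  }
  invisible(x)
}

#' Write a scan report as JSON
#'
#' @param report a `scan_report` from [profile_source()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(report, path) {
  stopifnot(inherits(report, "scan_report"))
  jsonlite::write_json(
    list(
      top_k = report$top_k,
      tables = lapply(unname(report$tables), function(tb) {
        list(
          name = tb$name, row_count = tb$row_count,
          columns = lapply(unname(tb$columns), function(cl) {
            list(name = cl$name, type = cl$type,
                 fraction_missing = cl$fraction_missing,
                 frequencies = cl$frequencies)
          })
        )
      })
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
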