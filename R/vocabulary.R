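# Concept store and vocabulary mapping: classify local codes into mapping
# states S1/S2/S3, suggest candidate standard concepts by lexical
# similarity, and import mappable local codes as new concepts.
#
# States of a local vocabulary code against the OMOP-style vocabularies:
#   S1 - the code is present verbatim in a compatible vocabulary and
#        resolves directly to a standard concept (it is standard itself, or
#        carries a "Maps to" relationship to one).
#   S2 - no direct one-to-one presence, but a semantically equivalent
#        standard concept exists: either the verbatim concept is deprecated
#        and a "Concept replaced by" chain leads to one, or a manual hint
#        (the USAGI-style human-curated mapping) supplies one.
#   S3 - no equivalent standard concept exists.

#' Construct a concept store
#'
#' Holds OMOP-style vocabulary content: concepts, concept relationships and
#' vocabularies. Invariants are enforced: unique `concept_id`, unique
#' (`vocabulary_id`, `concept_code`) pairs, relationship endpoints that
#' resolve, no duplicate relationship triples, and vocabulary ids that exist
#' in the vocabulary table.
#'
#' @param concept tibble with columns `concept_id` (integer),
#'   `concept_name`, `domain_id`, `vocabulary_id`, `concept_code`,
#'   `is_standard` (logical).
#' @param concept_relationship tibble with columns `concept_id_1`,
#'   `concept_id_2`, `relationship_id`.
#' @param vocabulary tibble with columns `vocabulary_id`, `vocabulary_name`,
#'   `vocabulary_version`.
#' @return A `concept_store`.
#' @export
concept_store <- function(concept = NULL, concept_relationship = NULL,
                          vocabulary = NULL) {
  concept <- tibble::as_tibble(concept %||% tibble::tibble(
    concept_id = integer(0), concept_name = character(0),
    domain_id = character(0), vocabulary_id = character(0),
    concept_code = character(0), is_standard = logical(0)
  ))
  concept$concept_id <- as.integer(concept$concept_id)
  concept$is_standard <- as.logical(concept$is_standard)
  concept_relationship <- tibble::as_tibble(concept_relationship %||% tibble::tibble(
    concept_id_1 = integer(0), concept_id_2 = integer(0),
    relationship_id = character(0)
  ))
  concept_relationship$concept_id_1 <- as.integer(concept_relationship$concept_id_1)
  concept_relationship$concept_id_2 <- as.integer(concept_relationship$concept_id_2)
  vocabulary <- tibble::as_tibble(vocabulary %||% tibble::tibble(
    vocabulary_id = character(0), vocabulary_name = character(0),
    vocabulary_version = character(0)
  ))
  store <- structure(
    list(concept = concept, concept_relationship = concept_relationship,
         vocabulary = vocabulary),
    class = "concept_store"
  )
  validate_concept_store(store)
}

#' Validate a concept store
#'
#' @param store a `concept_store`.
#' @return `store`, for chaining; invariant violations are fatal.
#' @export
validate_concept_store <- function(store) {
  stopifnot(inherits(store, "concept_store"))
  cp <- store$concept
  if (anyDuplicated(cp$concept_id)) {
    stop_omopetl("duplicate concept_id: ",
                 paste(unique(cp$concept_id[duplicated(cp$concept_id)]), collapse = ", "))
  }
  key <- paste(cp$vocabulary_id, cp$concept_code, sep = "\r")
  if (anyDuplicated(key)) {
    stop_omopetl("duplicate (vocabulary_id, concept_code) pair in concept table")
  }
  if (any(is.na(cp$is_standard))) stop_omopetl("concept.is_standard must be TRUE/FALSE")
  missing_vocab <- setdiff(unique(cp$vocabulary_id), store$vocabulary$vocabulary_id)
  if (length(missing_vocab) > 0L) {
    stop_omopetl("concept rows reference unknown vocabulary_id: ",
                 paste(missing_vocab, collapse = ", "))
  }
  cr <- store$concept_relationship
  unresolved <- setdiff(c(cr$concept_id_1, cr$concept_id_2), cp$concept_id)
  if (length(unresolved) > 0L) {
    stop_omopetl("relationship endpoints do not resolve: ",
                 paste(unresolved, collapse = ", "))
  }
  triple <- paste(cr$concept_id_1, cr$concept_id_2, cr$relationship_id, sep = "\r")
  if (anyDuplicated(triple)) {
    stop_omopetl("duplicate (source, target, kind) relationship triples")
  }
  store
}

#' @export
print.concept_store <- function(x, ...) {
  cat("<concept_store>\n")
  cat("  concepts:     ", nrow(x$concept),
      " (", sum(x$concept$is_standard), " standard)\n", sep = "")
  cat("  relationships:", nrow(x$concept_relationship), "\n")
  cat("  vocabularies: ", nrow(x$vocabulary), "\n")
  invisible(x)
}

# ---- Athena-style IO ------------------------------------------------------

#' Read a concept store from Athena-style files
#'
#' Reads `CONCEPT.csv`, `CONCEPT_RELATIONSHIP.csv` and `VOCABULARY.csv`
#' (tab-separated, OMOP vocabulary-table column layout, as distributed by
#' Athena) from `dir`. The `standard_concept` flag `"S"` maps to
#' `is_standard = TRUE`.
#'
#' @param dir directory holding the three files.
#' @return A [concept_store()].
#' @export
read_concept_store <- function(dir) {
  read_tsv0 <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop_omopetl("concept store file not found: ", path)
    readr::read_delim(path, delim = "\t",
                      col_types = readr::cols(.default = readr::col_character()),
                      na = character(0), progress = FALSE, show_col_types = FALSE)
  }
  cp <- read_tsv0("CONCEPT.csv")
  cr <- read_tsv0("CONCEPT_RELATIONSHIP.csv")
  vb <- read_tsv0("VOCABULARY.csv")
  concept_store(
    concept = tibble::tibble(
      concept_id = as.integer(cp$concept_id),
      concept_name = cp$concept_name,
      domain_id = cp$domain_id,
      vocabulary_id = cp$vocabulary_id,
      concept_code = cp$concept_code,
      is_standard = cp$standard_concept == "S"
    ),
    concept_relationship = tibble::tibble(
      concept_id_1 = as.integer(cr$concept_id_1),
      concept_id_2 = as.integer(cr$concept_id_2),
      relationship_id = cr$relationship_id
    ),
    vocabulary = tibble::tibble(
      vocabulary_id = vb$vocabulary_id,
      vocabulary_name = vb$vocabulary_name,
      vocabulary_version = vb$vocabulary_version
    )
  )
}

#' Write a concept store as Athena-style files
#'
#' Emits tab-separated `CONCEPT.csv`, `CONCEPT_RELATIONSHIP.csv` and
#' `VOCABULARY.csv` with the OMOP vocabulary-table column layout
#' (placeholder `concept_class_id` and validity dates, `standard_concept`
#' `"S"` for standard concepts). [read_concept_store()] round-trips.
#'
#' @param store a `concept_store`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_concept_store <- function(store, dir) {
  stopifnot(inherits(store, "concept_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cp <- store$concept
  concept_out <- tibble::tibble(
    concept_id = cp$concept_id,
    concept_name = cp$concept_name,
    domain_id = cp$domain_id,
    vocabulary_id = cp$vocabulary_id,
    concept_class_id = "Undefined",
    standard_concept = ifelse(cp$is_standard, "S", ""),
    concept_code = cp$concept_code,
    valid_start_date = "1970-01-01",
    valid_end_date = "2099-12-31",
    invalid_reason = ""
  )
  cr <- store$concept_relationship
  rel_out <- tibble::tibble(
    concept_id_1 = cr$concept_id_1,
    concept_id_2 = cr$concept_id_2,
    relationship_id = cr$relationship_id,
    valid_start_date = "1970-01-01",
    valid_end_date = "2099-12-31",
    invalid_reason = ""
  )
  vb <- store$vocabulary
  vocab_out <- tibble::tibble(
    vocabulary_id = vb$vocabulary_id,
    vocabulary_name = vb$vocabulary_name,
    vocabulary_reference = "",
    vocabulary_version = vb$vocabulary_version,
    vocabulary_concept_id = 0L
  )
  readr::write_tsv(concept_out, file.path(dir, "CONCEPT.csv"), na = "", progress = FALSE)
  readr::write_tsv(rel_out, file.path(dir, "CONCEPT_RELATIONSHIP.csv"), na = "", progress = FALSE)
  readr::write_tsv(vocab_out, file.path(dir, "VOCABULARY.csv"), na = "", progress = FALSE)
  invisible(dir)
}

# ---- classification -------------------------------------------------------

#' Default local-to-OMOP vocabulary compatibility map
#'
#' Maps each local (source) vocabulary id to the ordered list of OMOP-style
#' vocabulary ids in which verbatim membership is checked. Order encodes
#' precedence: for Austrian ICD-10 (`ICD10-BMSG`) the WHO edition is checked
#' before the US Clinical Modification, so a code present in both resolves
#' through the WHO variant. Local vocabularies not listed here are checked
#' against a vocabulary of their own id.
#'
#' @return Named list of character vectors.
#' @export
default_vocab_compat <- function() {
  list(
    "ICD10-BMSG"        = c("ICD10", "ICD10CM"),
    "ATC-AT"            = "ATC",
    "PRN"               = c("RxNorm", "RxNorm Extension"),
    "ProfessionalGroup" = "Medicare Specialty",
    "SEI"               = "SNOMED"
  )
}

# Resolve a concept id directly to a standard concept id: itself when
# standard, otherwise the smallest-id standard target of a "Maps to" edge.
.resolve_standard <- function(concept_id, store) {
  cp <- store$concept
  row <- match(concept_id, cp$concept_id)
  if (is.na(row)) return(NA_integer_)
  if (isTRUE(cp$is_standard[[row]])) return(cp$concept_id[[row]])
  cr <- store$concept_relationship
  targets <- cr$concept_id_2[cr$concept_id_1 == concept_id &
                               cr$relationship_id == "Maps to"]
  targets <- targets[cp$is_standard[match(targets, cp$concept_id)]]
  if (length(targets) == 0L) return(NA_integer_)
  min(targets)
}

# Follow "Concept replaced by" edges transitively (cycle-safe, breadth
# first), returning the first reachable concept that resolves to a standard
# concept; ties at the same depth break by ascending concept id.
.resolve_replacement <- function(concept_id, store) {
  cr <- store$concept_relationship
  seen <- concept_id
  frontier <- concept_id
  while (length(frontier) > 0L) {
    nxt <- sort(unique(cr$concept_id_2[cr$concept_id_1 %in% frontier &
                                         cr$relationship_id == "Concept replaced by"]))
    nxt <- setdiff(nxt, seen)
    for (cid in nxt) {
      sc <- .resolve_standard(cid, store)
      if (!is.na(sc)) return(sc)
    }
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  NA_integer_
}

.normalize_hints <- function(hints) {
  if (is.null(hints)) {
    return(tibble::tibble(local_code = character(0),
                          local_vocabulary_id = character(0),
                          standard_concept_id = integer(0)))
  }
  hints <- tibble::as_tibble(hints)
  if (!all(c("local_code", "standard_concept_id") %in% names(hints))) {
    stop_omopetl("hints need columns local_code and standard_concept_id")
  }
  if (!"local_vocabulary_id" %in% names(hints)) {
    hints$local_vocabulary_id <- NA_character_
  }
  hints$standard_concept_id <- as.integer(hints$standard_concept_id)
  hints[c("local_code", "local_vocabulary_id", "standard_concept_id")]
}

#' Classify one local code into state S1/S2/S3
#'
#' Determines the mapping state of a local vocabulary code against the
#' concept store. The code is first looked up verbatim in each compatible
#' vocabulary, in precedence order. A verbatim concept that resolves
#' directly to a standard concept yields S1. A verbatim but deprecated
#' concept whose "Concept replaced by" chain reaches a standard concept, or
#' a manual hint supplying an equivalent standard concept, yields S2.
#' Otherwise the code is S3 and carries no standard concept.
#'
#' @param code local code string (non-empty).
#' @param vocab_id local vocabulary id (e.g. `"ICD10-BMSG"`).
#' @param store a [concept_store()].
#' @param hints optional tibble of manual mappings with columns
#'   `local_code`, `standard_concept_id` and optionally
#'   `local_vocabulary_id`.
#' @param compat vocabulary compatibility map, see [default_vocab_compat()].
#' @return One-row tibble: `local_code`, `local_vocabulary_id`, `state`
#'   (`"S1"`/`"S2"`/`"S3"`), `standard_concept_id` (`NA` for S3),
#'   `matched_concept_id` (the verbatim concept hit, if any) and `evidence`
#'   (`"verbatim"`, `"replacement"`, `"hint"` or `"none"`).
#' @export
classify_code <- function(code, vocab_id, store, hints = NULL,
                          compat = default_vocab_compat()) {
  if (is.na(code) || !nzchar(code)) stop_omopetl("empty code")
  stopifnot(inherits(store, "concept_store"))
  hints <- .normalize_hints(hints)
  cp <- store$concept
  vocabs <- compat[[vocab_id]] %||% vocab_id

  matched <- NA_integer_
  for (vb in vocabs) {
    hit <- cp$concept_id[cp$vocabulary_id == vb & cp$concept_code == code]
    if (length(hit) > 0L) {
      matched <- min(hit)
      break
    }
  }

  state <- "S3"
  standard <- NA_integer_
  evidence <- "none"
  if (!is.na(matched)) {
    standard <- .resolve_standard(matched, store)
    if (!is.na(standard)) {
      state <- "S1"
      evidence <- "verbatim"
    } else {
      standard <- .resolve_replacement(matched, store)
      if (!is.na(standard)) {
        state <- "S2"
        evidence <- "replacement"
      }
    }
  }
  if (state == "S3") {
    hrow <- which(hints$local_code == code &
                    (is.na(hints$local_vocabulary_id) |
                       hints$local_vocabulary_id == vocab_id))
    if (length(hrow) > 0L) {
      target <- hints$standard_concept_id[[hrow[[1L]]]]
      resolved <- .resolve_standard(target, store)
      if (is.na(resolved)) {
        stop_omopetl("hint for code '", code, "' targets concept ", target,
                     " which does not resolve to a standard concept")
      }
      state <- "S2"
      standard <- resolved
      evidence <- "hint"
    }
  }
  tibble::tibble(
    local_code = code, local_vocabulary_id = vocab_id, state = state,
    standard_concept_id = standard, matched_concept_id = matched,
    evidence = evidence
  )
}

#' Classify a list of local codes and summarize states
#'
#' Applies [classify_code()] to every distinct (`code`, `vocab_id`) pair.
#' Duplicate pairs are collapsed with a warning. Every code lands in exactly
#' one state; state fractions sum to 1 for non-empty input.
#'
#' @param codes tibble with columns `code` and `vocab_id` (one row per local
#'   code), or a character vector with `vocab_id` given separately.
#' @param store a [concept_store()].
#' @param hints,compat see [classify_code()].
#' @param vocab_id used when `codes` is a bare character vector.
#' @return A `vocab_classification`: list with `assessments` (per-code
#'   tibble) and `summary` (per-state `n` and `fraction`).
#' @export
classify_vocabulary <- function(codes, store, hints = NULL,
                                compat = default_vocab_compat(),
                                vocab_id = NULL) {
  if (is.character(codes)) {
    if (is.null(vocab_id)) stop_omopetl("vocab_id required for a bare code vector")
    codes <- tibble::tibble(code = codes, vocab_id = vocab_id)
  }
  codes <- tibble::as_tibble(codes)
  stopifnot(all(c("code", "vocab_id") %in% names(codes)))
  key <- paste(codes$vocab_id, codes$code, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (code, vocab_id) entries collapsed", call. = FALSE)
    codes <- codes[!duplicated(key), , drop = FALSE]
  }
  assessments <- purrr::pmap_dfr(
    list(codes$code, codes$vocab_id),
    function(code, vb) classify_code(code, vb, store, hints, compat)
  )
  if (nrow(assessments) == 0L) {
    assessments <- classify_code("_", "_", concept_store())[0L, ]
    summary <- tibble::tibble(state = character(0), n = integer(0),
                              fraction = numeric(0))
  } else {
    summary <- tibble::tibble(state = c("S1", "S2", "S3")) |>
      dplyr::left_join(dplyr::count(assessments, .data$state), by = "state") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                    fraction = .data$n / nrow(assessments))
  }
  structure(list(assessments = assessments, summary = summary),
            class = "vocab_classification")
}

#' @export
print.vocab_classification <- function(x, ...) {
  cat("<vocab_classification> ", nrow(x$assessments), " codes\n", sep = "")
  print(x$summary)
  invisible(x)
}

# ---- candidate suggestion -------------------------------------------------

.normalize_term <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

# Character trigram set over the token set of a normalized name; tokens
# shorter than three characters contribute themselves.
.trigram_set <- function(norm) {
  tokens <- unique(strsplit(norm, " ", fixed = TRUE)[[1L]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) return(character(0))
  grams <- lapply(tokens, function(tk) {
    n <- nchar(tk)
    if (n < 3L) tk else substring(tk, 1:(n - 2L), 3:n)
  })
  unique(unlist(grams))
}

.trigram_jaccard <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

#' Suggest candidate standard concepts for a free-text term
#'
#' USAGI-style lexical matching: ranks concepts by token-set trigram
#' similarity (Jaccard on character trigrams of the lower-cased,
#' punctuation-stripped token set) between the query term and each concept
#' name. The ranking is deterministic: score descending, ties broken by
#' ascending concept id; zero-score candidates are omitted. A term identical
#' to a concept name scores 1.
#'
#' @param term free-text name to map (non-empty).
#' @param store a [concept_store()].
#' @param k maximum number of candidates to return (>= 1).
#' @param domain_filter optional domain id restricting the searched
#'   concepts (e.g. `"Provider Specialty"`).
#' @param standard_only restrict candidates to standard concepts (default).
#' @return Tibble `concept_id`, `score`, `matched_name`, at most `k` rows.
#' @export
suggest_candidates <- function(term, store, k = 10L, domain_filter = NULL,
                               standard_only = TRUE) {
  if (is.na(term) || !nzchar(trimws(term))) stop_omopetl("empty term")
  stopifnot(k >= 1L, inherits(store, "concept_store"))
  cp <- store$concept
  if (standard_only) cp <- cp[cp$is_standard, , drop = FALSE]
  if (!is.null(domain_filter)) cp <- cp[cp$domain_id %in% domain_filter, , drop = FALSE]
  q <- .trigram_set(.normalize_term(term))
  scores <- vapply(cp$concept_name, function(nm) {
    .trigram_jaccard(q, .trigram_set(.normalize_term(nm)))
  }, numeric(1), USE.NAMES = FALSE)
  keep <- scores > 0
  out <- tibble::tibble(concept_id = cp$concept_id[keep],
                        score = scores[keep],
                        matched_name = cp$concept_name[keep])
  out <- out[order(-out$score, out$concept_id), , drop = FALSE]
  out[seq_len(min(nrow(out), k)), , drop = FALSE]
}

# ---- import ---------------------------------------------------------------

#' Import classified local codes as new concepts
#'
#' Adds every S1/S2 assessment to the store as a new non-standard concept in
#' its local vocabulary, with exactly one `"Maps to"` relationship to its
#' resolved standard concept. New concept ids come from a reserved local
#' range (OHDSI convention: ids from two billion), assigned sequentially in
#' sorted (`local_vocabulary_id`, `local_code`) order, so imports are
#' deterministic. S3 codes are never imported and are listed in the report.
#' The operation is idempotent: codes whose (`vocabulary_id`,
#' `concept_code`) already exist in the store are skipped.
#'
#' @param assessments tibble of assessments as returned by
#'   [classify_code()]/[classify_vocabulary()].
#' @param store a [concept_store()].
#' @param id_start first concept id of the reserved local range.
#' @return List with the updated `store` and a `report` (tibbles `imported`,
#'   `skipped`, `unimported`).
#' @export
import_local_vocabulary <- function(assessments, store,
                                    id_start = 2000000000L) {
  if (inherits(assessments, "vocab_classification")) {
    assessments <- assessments$assessments
  }
  assessments <- tibble::as_tibble(assessments)
  stopifnot(inherits(store, "concept_store"))
  needed <- c("local_code", "local_vocabulary_id", "state", "standard_concept_id")
  stopifnot(all(needed %in% names(assessments)))
  mappable <- assessments[assessments$state %in% c("S1", "S2"), , drop = FALSE]
  if (any(is.na(mappable$standard_concept_id))) {
    bad <- mappable$local_code[is.na(mappable$standard_concept_id)]
    stop_omopetl("S1/S2 assessment without standard_concept_id: ",
                 paste(bad, collapse = ", "))
  }
  unimported <- assessments[assessments$state == "S3",
                            c("local_code", "local_vocabulary_id"), drop = FALSE]
  mappable <- mappable[order(mappable$local_vocabulary_id, mappable$local_code), ,
                       drop = FALSE]
  cp <- store$concept
  existing_key <- paste(cp$vocabulary_id, cp$concept_code, sep = "\r")
  key <- paste(mappable$local_vocabulary_id, mappable$local_code, sep = "\r")
  present <- key %in% existing_key
  skipped <- mappable[present, c("local_code", "local_vocabulary_id"), drop = FALSE]
  todo <- mappable[!present, , drop = FALSE]

  used_local <- cp$concept_id[cp$concept_id >= id_start]
  next_id <- if (length(used_local) == 0L) id_start else max(used_local) + 1L
  new_ids <- if (nrow(todo)) seq.int(next_id, length.out = nrow(todo)) else integer(0)

  new_concepts <- tibble::tibble(
    concept_id = as.integer(new_ids),
    concept_name = todo$local_code,
    domain_id = store$concept$domain_id[match(todo$standard_concept_id,
                                              store$concept$concept_id)],
    vocabulary_id = todo$local_vocabulary_id,
    concept_code = todo$local_code,
    is_standard = FALSE
  )
  new_rels <- tibble::tibble(
    concept_id_1 = as.integer(new_ids),
    concept_id_2 = as.integer(todo$standard_concept_id),
    relationship_id = rep("Maps to", nrow(todo))
  )
  new_vocab_ids <- setdiff(unique(todo$local_vocabulary_id),
                           store$vocabulary$vocabulary_id)
  new_vocabs <- tibble::tibble(
    vocabulary_id = new_vocab_ids,
    vocabulary_name = paste(new_vocab_ids, "(local)"),
    vocabulary_version = "local-import"
  )
  updated <- concept_store(
    concept = dplyr::bind_rows(store$concept, new_concepts),
    concept_relationship = dplyr::bind_rows(store$concept_relationship, new_rels),
    vocabulary = dplyr::bind_rows(store$vocabulary, new_vocabs)
  )
  report <- list(
    imported = tibble::tibble(
      local_code = todo$local_code,
      local_vocabulary_id = todo$local_vocabulary_id,
      concept_id = as.integer(new_ids),
      standard_concept_id = as.integer(todo$standard_concept_id)
    ),
    skipped = skipped,
    unimported = unimported
  )
  list(store = updated, report = report)
}
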