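# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the optimized implementations.

# Exhaustive group-and-count duplicate oracle: number of rows beyond the
# first in every group of identical key tuples.
oracle_dup_count <- function(df, cols) {
  if (nrow(df) == 0L) return(0L)
  keys <- rep("", nrow(df))
  for (cl in cols) {
    v <- as.character(df[[cl]])
    v[is.na(v)] <- "\x01NA"
    keys <- paste(keys, v, sep = "\x02")
  }
  sum(table(keys) - 1L)
}

# Brute-force state classifier: linear membership scan over the concept
# table, then exhaustive relationship traversal, mirroring the definition
# of the states rather than the package's code path.
oracle_classify_state <- function(code, vocab_id, store, hints = NULL,
                                  compat = default_vocab_compat()) {
  cp <- as.data.frame(store$concept)
  cr <- as.data.frame(store$concept_relationship)
  vocabs <- compat[[vocab_id]]
  if (is.null(vocabs)) vocabs <- vocab_id
  matched <- NA_integer_
  for (vb in vocabs) {
    found <- c()
    for (i in seq_len(nrow(cp))) {
      if (cp$vocabulary_id[i] == vb && cp$concept_code[i] == code) {
        found <- c(found, cp$concept_id[i])
      }
    }
    if (length(found) > 0L) {
      matched <- min(found)
      break
    }
  }
  direct_standard <- function(cid) {
    row <- which(cp$concept_id == cid)
    if (length(row) == 1L && cp$is_standard[row]) return(cid)
    best <- NA_integer_
    for (i in seq_len(nrow(cr))) {
      if (cr$concept_id_1[i] == cid && cr$relationship_id[i] == "Maps to") {
        trow <- which(cp$concept_id == cr$concept_id_2[i])
        if (cp$is_standard[trow] && (is.na(best) || cr$concept_id_2[i] < best)) {
          best <- cr$concept_id_2[i]
        }
      }
    }
    best
  }
  if (!is.na(matched)) {
    std <- direct_standard(matched)
    if (!is.na(std)) return(list(state = "S1", standard = std))
    # exhaustive walk over replacement chains
    seen <- matched
    frontier <- matched
    while (length(frontier) > 0L) {
      nxt <- c()
      for (i in seq_len(nrow(cr))) {
        if (cr$concept_id_1[i] %in% frontier &&
            cr$relationship_id[i] == "Concept replaced by" &&
            !(cr$concept_id_2[i] %in% seen)) {
          nxt <- c(nxt, cr$concept_id_2[i])
        }
      }
      nxt <- sort(unique(nxt))
      for (cid in nxt) {
        std <- direct_standard(cid)
        if (!is.na(std)) return(list(state = "S2", standard = std))
      }
      seen <- c(seen, nxt)
      frontier <- nxt
    }
  }
  if (!is.null(hints)) {
    h <- as.data.frame(hints)
    for (i in seq_len(nrow(h))) {
      vok <- !("local_vocabulary_id" %in% names(h)) ||
        is.na(h$local_vocabulary_id[i]) || h$local_vocabulary_id[i] == vocab_id
      if (h$local_code[i] == code && vok) {
        std <- direct_standard(as.integer(h$standard_concept_id[i]))
        if (!is.na(std)) return(list(state = "S2", standard = std))
      }
    }
  }
  list(state = "S3", standard = NA_integer_)
}

# Independent trigram similarity (double loop, substr-based).
oracle_similarity <- function(a, b) {
  grams <- function(s) {
    s <- tolower(s)
    s <- gsub("[^a-z0-9]+", " ", s)
    out <- character(0)
    for (tok in unique(strsplit(trimws(s), " +")[[1]])) {
      if (nchar(tok) == 0L) next
      if (nchar(tok) < 3L) {
        out <- c(out, tok)
      } else {
        for (i in 1:(nchar(tok) - 2L)) out <- c(out, substr(tok, i, i + 2L))
      }
    }
    unique(out)
  }
  ga <- grams(a)
  gb <- grams(b)
  if (length(ga) == 0L || length(gb) == 0L) return(0)
  length(intersect(ga, gb)) / length(union(ga, gb))
}

# Straight-line recomputation of the descriptive indicators from raw
# source tables (deduplicated stays), used as the stats oracle.
oracle_stats <- function(ds, ref_year = 2008L) {
  pat <- as.data.frame(ds$patient)
  stays <- as.data.frame(ds$hospital_stay)
  stays <- stays[!duplicated(stays[c("patient_key", "admission_date",
                                     "discharge_date")]), ]
  rx <- as.data.frame(ds$prescription)
  lomed <- function(x) {
    x <- sort(x[!is.na(x)])
    if (length(x) == 0L) return(NA_real_)
    x[ceiling(length(x) / 2)]
  }
  hosp <- as.integer(table(stays$patient_key))
  rxn <- as.integer(table(rx$patient_key))
  list(
    percent_female = 100 * sum(pat$sex_code == "F", na.rm = TRUE) / nrow(pat),
    median_age = lomed(ref_year - pat$birth_year),
    median_hospitalizations = lomed(hosp),
    median_prescriptions = lomed(rxn),
    median_length_of_stay = lomed(as.numeric(stays$discharge_date -
                                               stays$admission_date))
  )
}

# Hand-built miniature store exercising the vocabulary-change pattern:
# the retired ATC code D11AX19 (alitretinoin) was replaced by D11AH04.
tiny_store <- function() {
  concept_store(
    concept = tibble::tibble(
      concept_id   = c(100L, 101L, 200L, 201L, 202L, 300L,
                       9201L, 8507L, 8532L),
      concept_name = c("cholera due to vibrio", "entity A00.1",
                       "alitretinoin", "entity D11AH04",
                       "entity D11AX19 (deprecated)", "insulin",
                       "Inpatient Visit", "MALE", "FEMALE"),
      domain_id    = c("Condition", "Metadata", "Drug", "Metadata",
                       "Metadata", "Drug", "Visit", "Gender", "Gender"),
      vocabulary_id = c("SNOMED", "ICD10", "RxNorm", "ATC", "ATC", "RxNorm",
                        "Visit", "Gender", "Gender"),
      concept_code = c("STD-100", "A00.1", "STD-200", "D11AH04", "D11AX19",
                       "STD-300", "IP", "M", "F"),
      is_standard  = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
                       TRUE, TRUE, TRUE)
    ),
    concept_relationship = tibble::tibble(
      concept_id_1 = c(101L, 201L, 202L),
      concept_id_2 = c(100L, 200L, 201L),
      relationship_id = c("Maps to", "Maps to", "Concept replaced by")
    ),
    vocabulary = tibble::tibble(
      vocabulary_id = c("SNOMED", "ICD10", "RxNorm", "ATC", "Visit", "Gender"),
      vocabulary_name = c("SNOMED (fixture)", "ICD10 (fixture)",
                          "RxNorm (fixture)", "ATC (fixture)",
                          "Visit (fixture)", "Gender (fixture)"),
      vocabulary_version = "test"
    )
  )
}

# Memoised full pipeline run (simulate -> classify -> import -> ETL), so
# several test files can assert different properties of the same runs
# without recomputing them.
pipeline_run <- local({
  cache <- new.env(parent = emptyenv())
  function(seed, n_patients = 500L) {
    key <- sprintf("seed%d_n%d", seed, n_patients)
    if (!exists(key, envir = cache, inherits = FALSE)) {
      gen <- generate_source(source_gen_config(n_patients = n_patients,
                                               seed = seed))
      fix <- generate_vocabulary_fixture(vocab_gen_config(seed = seed))
      cls <- assess_source_codes(gen$dataset, fix$store, fix$hints)
      imp <- import_local_vocabulary(cls, fix$store)
      res <- run_etl(gen$dataset, imp$store, cls, etl_config())
      assign(key, list(gen = gen, fix = fix, cls = cls, imp = imp,
                       cdm = res$cdm, report = res$report), envir = cache)
    }
    get(key, envir = cache, inherits = FALSE)
  }
})
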