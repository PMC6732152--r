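# Seeded generators for GAP-DRG-style claims source datasets and miniature
# OMOP-style concept-store fixtures with known ground truth. The generated
# world emulates the shape of Austrian claims data for an elderly cohort:
# patients over 70, ICD-10-like diagnosis codes, ATC-like drug codes,
# pharmaceutical registration numbers, prescriber professional groups (a
# few unmappable), socio-economic index with missingness, and injected
# byte-identical duplicate hospital-stay and diagnosis records.

#' Default local code pools
#'
#' Deterministic (seed-free) pools of plausible codes: ICD-10-like
#' diagnosis codes, ATC-like 7-character drug codes, PRN-like registration
#' numbers, and ten professional groups of which two (`"other facility"`,
#' `"transport service"`) have no specialty concept and stay unmappable.
#'
#' @param n_icd,n_atc,n_prn pool sizes.
#' @return Named list: `icd10`, `atc`, `prn`, `professional_groups`,
#'   `unmappable_groups`.
#' @export
default_code_pools <- function(n_icd = 50L, n_atc = 30L, n_prn = 60L) {
  icd <- sprintf("%s%02d.%d", LETTERS[(seq_len(n_icd) - 1L) %% 20L + 1L],
                 (seq_len(n_icd) * 7L) %% 100L, seq_len(n_icd) %% 10L)
  atc <- sprintf("%s%02d%s%s%02d",
                 c("A", "B", "C", "D", "G", "J", "M", "N", "R", "S")[(seq_len(n_atc) - 1L) %% 10L + 1L],
                 (seq_len(n_atc) * 3L) %% 100L,
                 LETTERS[(seq_len(n_atc) * 5L) %% 26L + 1L],
                 LETTERS[(seq_len(n_atc) * 11L) %% 26L + 1L],
                 (seq_len(n_atc) * 13L) %% 100L)
  prn <- sprintf("1-%05d", seq_len(n_prn) * 137L %% 100000L)
  groups <- c("general practitioner", "internal medicine", "neurology",
              "orthopedics", "dermatology", "ophthalmology", "urology",
              "pulmonology", "other facility", "transport service")
  list(icd10 = unique(icd), atc = unique(atc), prn = unique(prn),
       professional_groups = groups,
       unmappable_groups = c("other facility", "transport service"))
}

#' Configuration of the synthetic claims source generator
#'
#' Defaults state the emulated world: 500 patients aged 70--100 at study
#' start (elderly cohort), female probability 0.508, study period
#' 2008--2011, Zipf-like long-tail code usage, 5% injected duplicate rates
#' for hospital stays and diagnoses, and missing-field rates for SEI (10%)
#' and sex (2%).
#'
#' @param n_patients cohort size (>= 0).
#' @param age_range inclusive age range at study start.
#' @param p_female probability of sex code `"F"`.
#' @param p_death probability of a death record within the study period.
#' @param mean_prescriptions,mean_stays Poisson means per patient over the
#'   whole study period.
#' @param mean_diagnoses_per_stay Poisson mean of diagnoses per stay (plus
#'   ~1 ambulatory diagnosis per patient on average).
#' @param dup_rate_stays,dup_rate_diagnoses fraction of rows duplicated
#'   verbatim (accounting artifacts the ETL must remove).
#' @param missing_sei,missing_sex missing-field probabilities.
#' @param mean_length_of_stay Poisson mean of stay length in days.
#' @param code_pools see [default_code_pools()].
#' @param study_start,study_end study period bounds.
#' @param seed integer seed; the single source of randomness.
#' @return A `source_gen_config`.
#' @export
source_gen_config <- function(n_patients = 500L, age_range = c(70L, 100L),
                              p_female = 0.508, p_death = 0.15,
                              mean_prescriptions = 20, mean_stays = 2,
                              mean_diagnoses_per_stay = 2,
                              dup_rate_stays = 0.05, dup_rate_diagnoses = 0.05,
                              missing_sei = 0.10, missing_sex = 0.02,
                              mean_length_of_stay = 5,
                              code_pools = default_code_pools(),
                              study_start = "2008-01-01",
                              study_end = "2011-12-31", seed = 1L) {
  probs <- c(p_female = p_female, p_death = p_death,
             dup_rate_stays = dup_rate_stays,
             dup_rate_diagnoses = dup_rate_diagnoses,
             missing_sei = missing_sei, missing_sex = missing_sex)
  if (any(probs < 0 | probs > 1)) {
    stop_omopetl("probabilities must be in [0, 1]: ",
                 paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (n_patients < 0L) stop_omopetl("n_patients must be >= 0")
  stopifnot(length(age_range) == 2L, age_range[1L] <= age_range[2L])
  structure(
    list(n_patients = as.integer(n_patients), age_range = as.integer(age_range),
         p_female = p_female, p_death = p_death,
         mean_prescriptions = mean_prescriptions, mean_stays = mean_stays,
         mean_diagnoses_per_stay = mean_diagnoses_per_stay,
         dup_rate_stays = dup_rate_stays,
         dup_rate_diagnoses = dup_rate_diagnoses,
         missing_sei = missing_sei, missing_sex = missing_sex,
         mean_length_of_stay = mean_length_of_stay,
         code_pools = code_pools,
         study_start = as_date_strict(study_start, what = "study_start"),
         study_end = as_date_strict(study_end, what = "study_end"),
         seed = as.integer(seed)),
    class = "source_gen_config"
  )
}

# Zipf-like sampling: probability proportional to 1/rank.
.zipf_sample <- function(pool, n) {
  if (n == 0L) return(character(0))
  sample(pool, n, replace = TRUE, prob = 1 / seq_along(pool))
}

.random_dates <- function(n, from, to) {
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic claims source dataset
#'
#' Draws a seeded cohort under the configured world (see
#' [source_gen_config()]): patients with birth years placing them in the
#' configured age range at study start, deaths, Zipf-distributed
#' prescription and diagnosis codes, hospital stays inside the study
#' period, and verbatim duplicate stay/diagnosis rows injected at the
#' configured rates. Accidental duplicates are removed before injection, so
#' the ground truth lists exactly the duplicate rows an exhaustive scan
#' finds. The result always passes [validate_source_dataset()].
#'
#' @param config a [source_gen_config()].
#' @return List: `dataset` (a [source_dataset()]) and `ground_truth` (list
#'   with `duplicates`: tibble `table`, `kept_key`, `dup_key`).
#' @export
generate_source <- function(config = source_gen_config()) {
  stopifnot(inherits(config, "source_gen_config"))
  cp <- config$code_pools
  n <- config$n_patients
  with_seed(derive_seed(config$seed, "source"), {
    start_year <- as.integer(format(config$study_start, "%Y"))
    ages <- if (n == 0L) integer(0) else {
      span <- config$age_range[1L]:config$age_range[2L]
      # long-tail toward the younger end of the elderly range
      sample(span, n, replace = TRUE, prob = 1 / seq_along(span)^0.7)
    }
    sex <- ifelse(stats::runif(n) < config$p_female, "F", "M")
    sex[stats::runif(n) < config$missing_sex] <- NA_character_
    sei <- sample.int(5L, n, replace = TRUE)
    sei[stats::runif(n) < config$missing_sei] <- NA_integer_
    patient <- tibble::tibble(
      patient_key = sprintf("P%06d", seq_len(n)),
      birth_year = start_year - ages,
      sex_code = sex,
      sei = sei
    )
    died <- which(stats::runif(n) < config$p_death)
    death <- tibble::tibble(
      patient_key = patient$patient_key[died],
      death_date = .random_dates(length(died), config$study_start, config$study_end)
    )
    n_rx <- stats::rpois(n, config$mean_prescriptions)
    rx_pat <- rep(patient$patient_key, n_rx)
    m <- length(rx_pat)
    prescription <- tibble::tibble(
      patient_key = rx_pat,
      prescription_date = .random_dates(m, config$study_start, config$study_end),
      prn = .zipf_sample(cp$prn, m),
      atc_code = .zipf_sample(cp$atc, m),
      professional_group = .zipf_sample(cp$professional_groups, m)
    )
    n_stay <- stats::rpois(n, config$mean_stays)
    stay_pat <- rep(patient$patient_key, n_stay)
    k <- length(stay_pat)
    admission <- .random_dates(k, config$study_start, config$study_end)
    los <- stats::rpois(k, config$mean_length_of_stay)
    discharge <- pmin(admission + los, config$study_end)
    hospital_stay <- tibble::tibble(
      patient_key = stay_pat, admission_date = admission,
      discharge_date = discharge
    )
    # drop accidental full-tuple duplicates so injected ones are the only ones
    hospital_stay <- hospital_stay[!duplicated(hospital_stay), , drop = FALSE]
    hospital_stay <- tibble::tibble(
      stay_key = sprintf("S%07d", seq_len(nrow(hospital_stay))),
      hospital_stay
    )
    n_dg <- stats::rpois(nrow(hospital_stay), config$mean_diagnoses_per_stay)
    dg_stay <- rep(hospital_stay$stay_key, n_dg)
    srow <- match(dg_stay, hospital_stay$stay_key)
    dg_date <- hospital_stay$admission_date[srow] +
      vapply(pmax(as.integer(hospital_stay$discharge_date[srow] -
                               hospital_stay$admission_date[srow]), 0L) + 1L,
             function(w) sample.int(w, 1L) - 1L, integer(1))
    inpatient <- tibble::tibble(
      patient_key = hospital_stay$patient_key[srow],
      icd10_code = .zipf_sample(cp$icd10, length(dg_stay)),
      stay_ref = dg_stay,
      diag_date = dg_date
    )
    n_amb <- stats::rpois(n, 1)
    amb_pat <- rep(patient$patient_key, n_amb)
    ambulatory <- tibble::tibble(
      patient_key = amb_pat,
      icd10_code = .zipf_sample(cp$icd10, length(amb_pat)),
      stay_ref = rep(NA_character_, length(amb_pat)),
      diag_date = .random_dates(length(amb_pat), config$study_start, config$study_end)
    )
    diagnosis <- dplyr::bind_rows(inpatient, ambulatory)
    diagnosis <- diagnosis[!duplicated(diagnosis), , drop = FALSE]
    diagnosis <- tibble::tibble(
      diag_key = sprintf("D%07d", seq_len(nrow(diagnosis))),
      diagnosis
    )

    inject <- function(df, key_col, rate, prefix) {
      n_dup <- stats::rbinom(1L, nrow(df), rate)
      if (n_dup == 0L || nrow(df) == 0L) {
        return(list(df = df,
                    truth = tibble::tibble(kept_key = character(0),
                                           dup_key = character(0))))
      }
      idx <- sample.int(nrow(df), n_dup)  # without replacement: one copy each
      dup <- df[idx, , drop = FALSE]
      new_keys <- sprintf("%s%07d", prefix, nrow(df) + seq_len(n_dup))
      truth <- tibble::tibble(kept_key = dup[[key_col]], dup_key = new_keys)
      dup[[key_col]] <- new_keys
      list(df = dplyr::bind_rows(df, dup), truth = truth)
    }
    stay_inj <- inject(hospital_stay, "stay_key", config$dup_rate_stays, "S")
    diag_inj <- inject(diagnosis, "diag_key", config$dup_rate_diagnoses, "D")

    truth <- dplyr::bind_rows(
      tibble::tibble(table = rep("hospital_stay", nrow(stay_inj$truth)),
                     stay_inj$truth),
      tibble::tibble(table = rep("diagnosis", nrow(diag_inj$truth)),
                     diag_inj$truth)
    )
    ds <- source_dataset(patient, death, prescription,
                         stay_inj$df, diag_inj$df)
    list(dataset = ds, ground_truth = list(duplicates = truth))
  })
}

#' Configuration of the vocabulary-fixture generator
#'
#' @param f_s1,f_s2,f_s3 fractions of ICD-10-like and ATC-like local codes
#'   that are verbatim present (S1), replacement-linked (S2) and absent
#'   (S3); must sum to 1.
#' @param f_icd_cm fraction of S1 ICD codes placed only in the
#'   ICD10-CM-like vocabulary (the rest are WHO-like; echoes that a small
#'   minority of codes match only the Clinical Modification).
#' @param f_prn_hinted fraction of PRN codes given a manual hint (S2); the
#'   rest are S3.
#' @param n_distractors extra standard concepts with unrelated names, to
#'   exercise lexical candidate search.
#' @param seed integer seed.
#' @return A `vocab_gen_config`.
#' @export
vocab_gen_config <- function(f_s1 = 0.8, f_s2 = 0.1, f_s3 = 0.1,
                             f_icd_cm = 0.1, f_prn_hinted = 0.5,
                             n_distractors = 20L, seed = 1L) {
  if (abs(f_s1 + f_s2 + f_s3 - 1) > 1e-9) {
    stop_omopetl("f_s1 + f_s2 + f_s3 must equal 1")
  }
  if (any(c(f_s1, f_s2, f_s3, f_icd_cm, f_prn_hinted) < 0)) {
    stop_omopetl("fractions must be non-negative")
  }
  structure(
    list(f_s1 = f_s1, f_s2 = f_s2, f_s3 = f_s3, f_icd_cm = f_icd_cm,
         f_prn_hinted = f_prn_hinted, n_distractors = as.integer(n_distractors),
         seed = as.integer(seed)),
    class = "vocab_gen_config"
  )
}

.concept_words <- c("chronic", "acute", "renal", "cardiac", "pulmonary",
                    "hepatic", "cutaneous", "cerebral", "metabolic", "osseous",
                    "disorder", "insufficiency", "infection", "fracture",
                    "neoplasm", "measurement", "screening", "assessment",
                    "procedure", "therapy")

#' Generate a miniature concept-store fixture with ground truth
#'
#' Builds an OMOP-style concept store over the given local code pools, with
#' a known classification for every local code. S1 codes are present
#' verbatim (ICD codes in an ICD10-WHO-like vocabulary, a seeded minority
#' only in an ICD10-CM-like one; ATC codes in an ATC vocabulary) and map to
#' standard concepts (SNOMED-like for diagnoses, spread over the Condition
#' / Procedure / Measurement / Observation domains; RxNorm-like Drug
#' concepts for ATC). S2 codes exist only as deprecated concepts whose
#' "Concept replaced by" edge leads to a successor code's concept — the
#' vocabulary-change pattern by which an ATC code is retired and replaced.
#' S3 codes are absent. Professional groups get standard Provider Specialty
#' concepts plus manual hints for all but the unmappable groups; a seeded
#' fraction of PRNs get hints to drug-product concepts; SEI gets nothing
#' (always S3). The store also defines the inpatient visit concept (9201)
#' and the gender concepts (8507/8532) the ETL needs.
#'
#' @param config a [vocab_gen_config()].
#' @param code_pools see [default_code_pools()].
#' @return List: `store` (a [concept_store()]), `hints` (tibble
#'   `local_code`, `local_vocabulary_id`, `standard_concept_id`) and
#'   `ground_truth` (tibble `local_code`, `local_vocabulary_id`, `state`,
#'   `standard_concept_id`).
#' @export
generate_vocabulary_fixture <- function(config = vocab_gen_config(),
                                        code_pools = default_code_pools()) {
  stopifnot(inherits(config, "vocab_gen_config"))
  if (length(code_pools$icd10) == 0L || length(code_pools$atc) == 0L) {
    stop_omopetl("empty code pool")
  }
  with_seed(derive_seed(config$seed, "vocabulary"), {
    ids <- new.env()
    ids$next_id <- 1000L
    take_ids <- function(k) {
      out <- seq.int(ids$next_id, length.out = k)
      ids$next_id <- ids$next_id + k
      as.integer(out)
    }
    concepts <- list()
    rels <- list()
    hints <- list()
    truth <- list()
    add_concepts <- function(df) concepts[[length(concepts) + 1L]] <<- df
    add_rels <- function(df) rels[[length(rels) + 1L]] <<- df
    add_truth <- function(df) truth[[length(truth) + 1L]] <<- df

    split_states <- function(codes) {
      n <- length(codes)
      n1 <- round(config$f_s1 * n)
      n2 <- round(config$f_s2 * n)
      n2 <- min(n2, n - n1)
      shuffled <- sample(codes)
      list(s1 = shuffled[seq_len(n1)],
           s2 = if (n2 > 0L) shuffled[n1 + seq_len(n2)] else character(0),
           s3 = shuffled[setdiff(seq_len(n), seq_len(n1 + n2))])
    }
    rand_name <- function(k, suffix) {
      paste(sample(.concept_words, k, replace = TRUE)[seq_len(k)],
            sample(.concept_words, k, replace = TRUE), suffix)
    }

    # a local code family: verbatim vocabulary + standard concepts + states
    build_family <- function(codes, local_vocab, member_vocab_of, std_vocab,
                             std_domains, successor) {
      st <- split_states(codes)
      # S1: verbatim concept, "Maps to" a standard concept
      if (length(st$s1) > 0L) {
        std_ids <- take_ids(length(st$s1))
        add_concepts(tibble::tibble(
          concept_id = std_ids,
          concept_name = rand_name(length(st$s1), seq_along(st$s1)),
          domain_id = sample(std_domains, length(st$s1), replace = TRUE,
                             prob = if (length(std_domains) == 4L) c(0.7, 0.1, 0.1, 0.1) else NULL),
          vocabulary_id = std_vocab,
          concept_code = paste0("STD-", std_ids),
          is_standard = TRUE
        ))
        local_ids <- take_ids(length(st$s1))
        add_concepts(tibble::tibble(
          concept_id = local_ids,
          concept_name = paste("entity", st$s1),
          domain_id = "Metadata",
          vocabulary_id = member_vocab_of(st$s1),
          concept_code = st$s1,
          is_standard = FALSE
        ))
        add_rels(tibble::tibble(concept_id_1 = local_ids, concept_id_2 = std_ids,
                                relationship_id = "Maps to"))
        add_truth(tibble::tibble(local_code = st$s1,
                                 local_vocabulary_id = local_vocab,
                                 state = "S1", standard_concept_id = std_ids))
      }
      # S2: deprecated concept, replaced by a successor concept that maps on
      if (length(st$s2) > 0L) {
        std_ids <- take_ids(length(st$s2))
        add_concepts(tibble::tibble(
          concept_id = std_ids,
          concept_name = rand_name(length(st$s2), paste0("r", seq_along(st$s2))),
          domain_id = sample(std_domains, length(st$s2), replace = TRUE),
          vocabulary_id = std_vocab,
          concept_code = paste0("STD-", std_ids),
          is_standard = TRUE
        ))
        succ_codes <- successor(st$s2)
        succ_ids <- take_ids(length(st$s2))
        add_concepts(tibble::tibble(
          concept_id = succ_ids,
          concept_name = paste("entity", succ_codes),
          domain_id = "Metadata",
          vocabulary_id = member_vocab_of(st$s2),
          concept_code = succ_codes,
          is_standard = FALSE
        ))
        add_rels(tibble::tibble(concept_id_1 = succ_ids, concept_id_2 = std_ids,
                                relationship_id = "Maps to"))
        old_ids <- take_ids(length(st$s2))
        add_concepts(tibble::tibble(
          concept_id = old_ids,
          concept_name = paste("entity", st$s2, "(deprecated)"),
          domain_id = "Metadata",
          vocabulary_id = member_vocab_of(st$s2),
          concept_code = st$s2,
          is_standard = FALSE
        ))
        add_rels(tibble::tibble(concept_id_1 = old_ids, concept_id_2 = succ_ids,
                                relationship_id = "Concept replaced by"))
        add_truth(tibble::tibble(local_code = st$s2,
                                 local_vocabulary_id = local_vocab,
                                 state = "S2", standard_concept_id = std_ids))
      }
      if (length(st$s3) > 0L) {
        add_truth(tibble::tibble(local_code = st$s3,
                                 local_vocabulary_id = local_vocab,
                                 state = "S3",
                                 standard_concept_id = NA_integer_))
      }
    }

    icd_pool <- code_pools$icd10
    cm_only <- sample(icd_pool, round(config$f_icd_cm * length(icd_pool)))
    build_family(
      icd_pool, "ICD10-BMSG",
      member_vocab_of = function(codes) ifelse(codes %in% cm_only, "ICD10CM", "ICD10"),
      std_vocab = "SNOMED",
      std_domains = c("Condition", "Procedure", "Measurement", "Observation"),
      successor = function(codes) paste0(codes, "R")
    )
    build_family(
      code_pools$atc, "ATC-AT",
      member_vocab_of = function(codes) "ATC",
      std_vocab = "RxNorm",
      std_domains = "Drug",
      successor = function(codes) paste0(codes, "X")
    )

    # professional groups: standard specialty concepts + hints (manual step)
    groups <- code_pools$professional_groups
    mappable <- setdiff(groups, code_pools$unmappable_groups)
    spec_ids <- take_ids(length(mappable))
    add_concepts(tibble::tibble(
      concept_id = spec_ids,
      concept_name = mappable,
      domain_id = "Provider Specialty",
      vocabulary_id = "Medicare Specialty",
      concept_code = sprintf("SPEC%02d", seq_along(mappable)),
      is_standard = TRUE
    ))
    hints[[length(hints) + 1L]] <- tibble::tibble(
      local_code = mappable, local_vocabulary_id = "ProfessionalGroup",
      standard_concept_id = spec_ids
    )
    add_truth(tibble::tibble(local_code = mappable,
                             local_vocabulary_id = "ProfessionalGroup",
                             state = "S2", standard_concept_id = spec_ids))
    add_truth(tibble::tibble(local_code = code_pools$unmappable_groups,
                             local_vocabulary_id = "ProfessionalGroup",
                             state = "S3", standard_concept_id = NA_integer_))

    # PRNs: a seeded fraction manually hinted to drug products, rest S3
    prn <- code_pools$prn
    hinted <- sample(prn, round(config$f_prn_hinted * length(prn)))
    if (length(hinted) > 0L) {
      prod_ids <- take_ids(length(hinted))
      add_concepts(tibble::tibble(
        concept_id = prod_ids,
        concept_name = rand_name(length(hinted), "product"),
        domain_id = "Drug",
        vocabulary_id = "RxNorm Extension",
        concept_code = paste0("RXE-", prod_ids),
        is_standard = TRUE
      ))
      hints[[length(hints) + 1L]] <- tibble::tibble(
        local_code = hinted, local_vocabulary_id = "PRN",
        standard_concept_id = prod_ids
      )
      add_truth(tibble::tibble(local_code = hinted, local_vocabulary_id = "PRN",
                               state = "S2", standard_concept_id = prod_ids))
    }
    s3_prn <- setdiff(prn, hinted)
    add_truth(tibble::tibble(local_code = s3_prn, local_vocabulary_id = "PRN",
                             state = "S3", standard_concept_id = NA_integer_))

    if (config$n_distractors > 0L) {
      d_ids <- take_ids(config$n_distractors)
      add_concepts(tibble::tibble(
        concept_id = d_ids,
        concept_name = rand_name(config$n_distractors, paste0("d", seq_along(d_ids))),
        domain_id = "Observation",
        vocabulary_id = "SNOMED",
        concept_code = paste0("DIS-", d_ids),
        is_standard = TRUE
      ))
    }
    # ETL support concepts: inpatient visit and administrative genders
    add_concepts(tibble::tibble(
      concept_id = c(9201L, 8507L, 8532L),
      concept_name = c("Inpatient Visit", "MALE", "FEMALE"),
      domain_id = c("Visit", "Gender", "Gender"),
      vocabulary_id = c("Visit", "Gender", "Gender"),
      concept_code = c("IP", "M", "F"),
      is_standard = TRUE
    ))

    concept <- dplyr::bind_rows(concepts)
    vocab_ids <- sort(unique(concept$vocabulary_id))
    store <- concept_store(
      concept = concept,
      concept_relationship = dplyr::bind_rows(rels),
      vocabulary = tibble::tibble(
        vocabulary_id = vocab_ids,
        vocabulary_name = paste(vocab_ids, "(fixture)"),
        vocabulary_version = "fixture-1"
      )
    )
    list(store = store,
         hints = dplyr::bind_rows(hints),
         ground_truth = dplyr::bind_rows(truth))
  })
}

#' Classify every local code occurring in a source dataset
#'
#' Convenience orchestration: collects the distinct ICD-10, ATC, PRN and
#' professional-group codes of a source dataset, labels them with their
#' local vocabulary ids and runs [classify_vocabulary()].
#'
#' @param source a [source_dataset()].
#' @param store a [concept_store()].
#' @param hints,compat see [classify_code()].
#' @return A `vocab_classification`.
#' @export
assess_source_codes <- function(source, store, hints = NULL,
                                compat = default_vocab_compat()) {
  stopifnot(inherits(source, "source_dataset"))
  codes <- dplyr::bind_rows(
    tibble::tibble(code = unique(source$diagnosis$icd10_code),
                   vocab_id = "ICD10-BMSG"),
    tibble::tibble(code = unique(source$prescription$atc_code),
                   vocab_id = "ATC-AT"),
    tibble::tibble(code = unique(source$prescription$prn),
                   vocab_id = "PRN"),
    tibble::tibble(code = unique(source$prescription$professional_group),
                   vocab_id = "ProfessionalGroup")
  )
  codes <- codes[!is.na(codes$code), , drop = FALSE]
  classify_vocabulary(codes, store, hints, compat)
}
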