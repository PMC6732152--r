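test_that("classification assigns S1, S2 and S3 with the right evidence", {
  store <- tiny_store()
  # verbatim ICD-10 code -> S1, mapped standard concept
  s1 <- classify_code("A00.1", "ICD10-BMSG", store)
  expect_identical(s1$state, "S1")
  expect_identical(s1$standard_concept_id, 100L)
  expect_identical(s1$evidence, "verbatim")
  # retired ATC code with a replacement chain -> S2 via the successor
  s2 <- classify_code("D11AX19", "ATC-AT", store)
  expect_identical(s2$state, "S2")
  expect_identical(s2$standard_concept_id, 200L)
  expect_identical(s2$evidence, "replacement")
  # socio-economic index: no store entry, no hint -> S3, no standard concept
  s3 <- classify_code("SEI", "SEI", store)
  expect_identical(s3$state, "S3")
  expect_true(is.na(s3$standard_concept_id))
  # manual hint supplies the equivalent concept -> S2
  hint <- tibble::tibble(local_code = "other group",
                         standard_concept_id = 300L)
  h <- classify_code("other group", "ProfessionalGroup", store, hints = hint)
  expect_identical(h$state, "S2")
  expect_identical(h$standard_concept_id, 300L)
  expect_identical(h$evidence, "hint")
  expect_error(classify_code("", "ATC-AT", store), "empty code")
})

test_that("vocabulary summaries partition the codes and handle edge cases", {
  fix <- generate_vocabulary_fixture(
    vocab_gen_config(f_s1 = 0.7, f_s2 = 0.2, f_s3 = 0.1, seed = 2L),
    default_code_pools(n_icd = 10L, n_atc = 5L)
  )
  icd <- fix$ground_truth[fix$ground_truth$local_vocabulary_id == "ICD10-BMSG", ]
  cls <- classify_vocabulary(
    tibble::tibble(code = icd$local_code, vocab_id = "ICD10-BMSG"),
    fix$store, fix$hints
  )
  counts <- setNames(cls$summary$n, cls$summary$state)
  expect_identical(unname(counts[c("S1", "S2", "S3")]), c(7L, 2L, 1L))
  expect_equal(sum(cls$summary$fraction), 1)
  expect_identical(sum(cls$summary$n), nrow(icd))
  # duplicates collapse with a warning
  expect_warning(
    dup <- classify_vocabulary(
      tibble::tibble(code = rep(icd$local_code[1], 2), vocab_id = "ICD10-BMSG"),
      fix$store),
    "collapsed"
  )
  expect_identical(nrow(dup$assessments), 1L)
  # empty input gives an empty summary
  empty <- classify_vocabulary(
    tibble::tibble(code = character(0), vocab_id = character(0)), fix$store)
  expect_identical(nrow(empty$assessments), 0L)
  expect_identical(nrow(empty$summary), 0L)
})

test_that("classifier agrees with the brute-force oracle across seeds", {
  for (seed in 1:4) {
    fix <- generate_vocabulary_fixture(
      vocab_gen_config(f_s1 = 0.6, f_s2 = 0.2, f_s3 = 0.2, seed = seed),
      default_code_pools(n_icd = 12L, n_atc = 8L, n_prn = 10L)
    )
    gt <- fix$ground_truth
    for (i in seq_len(nrow(gt))) {
      got <- classify_code(gt$local_code[i], gt$local_vocabulary_id[i],
                           fix$store, fix$hints)
      want <- oracle_classify_state(gt$local_code[i], gt$local_vocabulary_id[i],
                                    fix$store, fix$hints)
      expect_identical(got$state, want$state)
      expect_identical(got$standard_concept_id, want$standard)
      # and both agree with the generator's ground truth
      expect_identical(got$state, gt$state[i])
    }
  }
})

test_that("candidate suggestion ranks by trigram similarity, deterministically", {
  store <- concept_store(
    concept = tibble::tibble(
      concept_id = c(11L, 12L, 13L),
      concept_name = c("alitretinoin", "tretinoin", "insulin"),
      domain_id = "Drug", vocabulary_id = "RxNorm",
      concept_code = c("a", "b", "c"), is_standard = TRUE
    ),
    vocabulary = tibble::tibble(vocabulary_id = "RxNorm",
                                vocabulary_name = "x", vocabulary_version = "1")
  )
  # identical name ranks first with score 1
  hit <- suggest_candidates("Alitretinoin", store, k = 3L)
  expect_identical(hit$concept_id[1], 11L)
  expect_equal(hit$score[1], 1)
  # no shared trigrams -> empty result
  expect_identical(nrow(suggest_candidates("zzzz qqqq", store, k = 5L)), 0L)
  # ranking equals exhaustive pairwise scoring by the independent oracle
  got <- suggest_candidates("alitretinoin oral", store, k = 3L)
  oracle <- sapply(store$concept$concept_name,
                   function(nm) oracle_similarity("alitretinoin oral", nm))
  keep <- which(oracle > 0)
  want_order <- keep[order(-oracle[keep], store$concept$concept_id[keep])]
  expect_identical(got$concept_id, store$concept$concept_id[want_order])
  expect_equal(got$score, unname(oracle[want_order]))
  expect_error(suggest_candidates("  ", store), "empty term")
})

test_that("candidate ranking is invariant to store row order", {
  fix <- generate_vocabulary_fixture(vocab_gen_config(seed = 4L))
  store <- fix$store
  shuffled <- store
  perm <- rev(seq_len(nrow(store$concept)))
  shuffled$concept <- store$concept[perm, ]
  for (term in c("chronic renal insufficiency", "cardiac assessment therapy")) {
    expect_identical(suggest_candidates(term, store, k = 8L),
                     suggest_candidates(term, shuffled, k = 8L))
  }
})

test_that("local import adds one concept and one Maps to edge per S1/S2 code", {
  store <- tiny_store()
  cls <- classify_vocabulary(
    tibble::tibble(code = c("A00.1", "D11AX19", "SEI"),
                   vocab_id = c("ICD10-BMSG", "ATC-AT", "SEI")),
    store
  )
  imp <- import_local_vocabulary(cls, store)
  expect_identical(nrow(imp$report$imported), 2L)
  expect_identical(imp$report$unimported$local_code, "SEI")
  new <- imp$store$concept[imp$store$concept$concept_id >= 2000000000L, ]
  expect_identical(nrow(new), 2L)
  expect_false(any(new$is_standard))
  # ids are deterministic: sorted (vocabulary_id, code) order
  expect_identical(new$vocabulary_id[order(new$concept_id)],
                   c("ATC-AT", "ICD10-BMSG"))
  # out-degree exactly 1 on "Maps to", target standard
  for (cid in new$concept_id) {
    rel <- imp$store$concept_relationship
    maps <- rel[rel$concept_id_1 == cid & rel$relationship_id == "Maps to", ]
    expect_identical(nrow(maps), 1L)
    target <- imp$store$concept[imp$store$concept$concept_id == maps$concept_id_2, ]
    expect_true(target$is_standard)
  }
  # idempotence: re-import adds nothing
  again <- import_local_vocabulary(cls, imp$store)
  expect_equal(again$store, imp$store)
  expect_identical(nrow(again$report$imported), 0L)
  expect_identical(nrow(again$report$skipped), 2L)
  # S2 assessment without a standard concept is an error
  broken <- cls$assessments
  broken$standard_concept_id[broken$state == "S2"] <- NA_integer_
  expect_error(import_local_vocabulary(broken, store), "standard_concept_id")
})

test_that("imported stores keep the Maps-to out-degree invariant at scale", {
  run <- pipeline_run(2L, n_patients = 100L)
  new <- run$imp$store$concept[run$imp$store$concept$concept_id >= 2000000000L, ]
  rel <- run$imp$store$concept_relationship
  std <- run$imp$store$concept$concept_id[run$imp$store$concept$is_standard]
  maps <- rel[rel$relationship_id == "Maps to" & rel$concept_id_1 %in% new$concept_id, ]
  expect_identical(nrow(maps), nrow(new))
  expect_true(all(maps$concept_id_2 %in% std))
  # every S1/S2 ground-truth code was imported, every S3 was not
  gt <- run$fix$ground_truth
  used <- unique(run$cls$assessments[, c("local_code", "local_vocabulary_id", "state")])
  mappable <- used[used$state %in% c("S1", "S2"), ]
  key <- paste(new$vocabulary_id, new$concept_code)
  expect_setequal(key, paste(mappable$local_vocabulary_id, mappable$local_code))
})

test_that("concept store round-trips through Athena-style files", {
  fix <- generate_vocabulary_fixture(vocab_gen_config(seed = 6L))
  dir <- withr::local_tempdir()
  write_concept_store(fix$store, dir)
  back <- read_concept_store(dir)
  expect_equal(back$concept, fix$store$concept)
  expect_equal(back$concept_relationship, fix$store$concept_relationship)
  expect_equal(back$vocabulary, fix$store$vocabulary)
  # invariant violations are rejected
  bad <- fix$store$concept
  bad$concept_id[2] <- bad$concept_id[1]
  expect_error(concept_store(bad, fix$store$concept_relationship,
                             fix$store$vocabulary), "duplicate concept_id")
})
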