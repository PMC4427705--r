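test_that("generation is balanced, deterministic and schema-valid", {
  sch <- load_schema()
  c4 <- generate_corpus(4L, c(30L, 80L), seed = 2L, schema = sch)
  types <- vapply(c4, function(r) r$profile$patient_type, character(1L))
  expect_setequal(types, c("cardiovascular", "neurological", "renal",
                           "respiratory"))
  c4b <- generate_corpus(4L, c(30L, 80L), seed = 2L, schema = sch)
  expect_identical(c4, c4b)  # same seed, same corpus
  expect_false(identical(c4, generate_corpus(4L, c(30L, 80L), seed = 3L)))
  for (seed in 1:5) {
    cc <- generate_corpus(3L, c(30L, 80L), seed = seed, schema = sch)
    for (rec in cc) {
      expect_length(rec$doc$labels, length(rec$doc$tokens))
      expect_true(all(rec$doc$labels %in% sch$id))
    }
  }
  expect_error(generate_corpus(2L, c(10L, 20L)), "infeasible")
})

test_that("a 100-document corpus covers most of the category inventory", {
  corpus <- generate_corpus(100L, c(30L, 120L), seed = 8L)
  labs <- unlist(lapply(corpus, function(r) r$doc$labels))
  expect_gte(length(unique(labs)), 30L)
  lens <- vapply(corpus, function(r) length(r$doc$tokens), integer(1L))
  expect_gte(min(lens), 30L)
})

test_that("trigger vocabularies are disjoint and drive the cue feature", {
  lex <- synthetic_lexicons()
  all_tokens <- unlist(lex)
  expect_false(anyDuplicated(all_tokens) > 0)
  expect_length(intersect(all_tokens, handoverNLP:::.na_words), 0L)
  corpus <- generate_corpus(2L, c(30L, 60L), seed = 4L)
  fm <- synthetic_features(corpus[[1L]]$doc)
  expect_equal(ncol(fm$cells), 4L)  # token, cue, location, label
  cue <- fm$cells[, 2L]
  lab <- fm_labels(fm)
  inside <- lab != 50L
  expect_true(all(cue[inside] == paste0("C", lab[inside])))
})

test_that("zero-rate corruption is the identity with an empty ledger", {
  corpus <- generate_corpus(2L, c(30L, 60L), seed = 6L)
  cfg <- corruption_config(0, 0, 0, seed = 6L)
  cor <- corrupt_transcript(corpus[[1L]]$doc, cfg)
  expect_identical(as.character(cor$tokens), corpus[[1L]]$doc$tokens)
  expect_equal(nrow(cor$ledger), 0L)
})

test_that("the alignment recovers the injection ledger exactly", {
  corpus <- generate_corpus(10L, c(30L, 90L), seed = 13L)
  cfg <- corruption_config(seed = 13L)
  for (rec in corpus) {
    cor <- corrupt_transcript(rec$doc, cfg)
    al <- align_words(token_sequence(rec$doc$tokens), cor$tokens)
    expect_equal(al$S, sum(cor$ledger$op == "substitution"))
    expect_equal(al$I, sum(cor$ledger$op == "insertion"))
    expect_equal(al$D, sum(cor$ledger$op == "deletion"))
  }
})

test_that("injected substitutions are phonetically similar correction candidates", {
  corpus <- generate_corpus(6L, c(30L, 90L), seed = 21L)
  cfg <- corruption_config(substitution_rate = 0.3, insertion_rate = 0,
                           deletion_rate = 0, seed = 21L)
  found <- 0L
  for (rec in corpus) {
    cor <- corrupt_transcript(rec$doc, cfg)
    if (nrow(cor$ledger) == 0L) next
    al <- align_words(token_sequence(rec$doc$tokens), cor$tokens)
    recs <- classify_substitutions(al)
    found <- found + nrow(recs)
    expect_true(all(recs$ps >= 75))
    expect_true(all(recs$correction_candidate))
  }
  expect_gt(found, 10L)
})

test_that("pooled corpus correctness tracks the injected corruption rate", {
  corpus <- generate_corpus(60L, c(30L, 90L), seed = 31L)
  cfg <- corruption_config(seed = 31L)
  aligns <- lapply(corpus, function(rec) {
    cor <- corrupt_transcript(rec$doc, cfg)
    align_words(token_sequence(rec$doc$tokens, rec$doc$doc_id), cor$tokens)
  })
  s <- corpus_correctness(aligns)
  # reference words not substituted or deleted are correct:
  injected <- sum(vapply(aligns, function(a) a$S + a$D, numeric(1L)))
  expect_equal(s$pooled_correct, s$total_ref_words - injected)
  expect_lt(abs(s$pooled_correctness - (1 - injected / s$total_ref_words)),
            1e-12)
})

test_that("phonetic confusions preserve the sound of the word", {
  for (w in c("morphine", "harris", "aspirin", "stable", "monitoring")) {
    cands <- phonetic_confusions(w)
    if (length(cands) == 0L) next
    for (cand in cands)
      expect_gte(phonetic_similarity(w, cand)$ps, 75)
  }
})

test_that("written corpora follow the documented directory layout", {
  dir <- file.path(tempdir(), "synthcorp")
  unlink(dir, recursive = TRUE)
  corpus <- generate_corpus(4L, c(30L, 60L), seed = 9L)
  write_corpus(corpus, dir, corruption_config(seed = 9L))
  expect_length(list.files(file.path(dir, "reference")), 4L)
  expect_length(list.files(file.path(dir, "speechrecognised")), 4L)
  expect_true(file.exists(file.path(dir, "corpus.crfpp")))
  mats <- read_crfpp(file.path(dir, "corpus.crfpp"))
  expect_length(mats, 4L)
  expect_equal(fm_tokens(mats[[1L]]), corpus[[1L]]$doc$tokens)
})
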