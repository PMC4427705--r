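test_that("phonetic similarity implements the normalized edit-distance formula", {
  expect_equal(phonetic_similarity("four", "for")$ps, 100)
  expect_equal(phonetic_similarity(c("a", "b"), c("a", "b"))$ps, 100)
  # direct recomputation with an independent edit-distance routine
  set.seed(17)
  words <- c("lane", "laine", "sign", "san", "mews", "meal", "pain", "pane",
             "echo", "ecco", "chart", "cart", "obs", "阿"  , "dose", "doze")
  words <- words[words != "阿"]
  for (i in 1:40) {
    pair <- sample(words, 2L)
    pm <- phonetic_similarity(pair[1L], pair[2L])
    a <- strsplit(pm$ref_code, "")[[1L]]
    b <- strsplit(pm$hyp_code, "")[[1L]]
    expected <- 100 * (1 - bf_edit_distance(a, b) / max(length(a), length(b)))
    expect_gte(pm$ps, expected)  # alternates may only raise similarity
    if (pm$ps > expected) expect_lte(pm$ps, 100)
  }
})

test_that("similarity is symmetric, reflexive and bounded", {
  set.seed(23)
  alphabet <- letters
  for (i in 1:60) {
    w1 <- paste(sample(alphabet, 4L, replace = TRUE), collapse = "")
    w2 <- paste(sample(alphabet, 4L, replace = TRUE), collapse = "")
    f <- phonetic_similarity(w1, w2)$ps
    expect_equal(f, phonetic_similarity(w2, w1)$ps)
    expect_gte(f, 0); expect_lte(f, 100)
    expect_equal(phonetic_similarity(w1, w1)$ps, 100)
  }
  # degenerate all-vowel words have empty codes
  expect_equal(phonetic_similarity("eau", "eau")$ps, 100)
  expect_equal(phonetic_similarity("4", "8")$ps, 0)
  expect_error(phonetic_similarity(character(0), "a"), "non-empty")
})

test_that("substitution units are merged and class flags are consistent", {
  ref <- c("patient", "in", "the", "years", "old", "doctors", "signed", "form")
  hyp <- c("patient", "and", "the", "yrs",  "old", "dr",      "san",    "form")
  al <- align_words(ref, hyp)
  recs <- classify_substitutions(al)
  # adjacent substitutions merge into one multi-word unit
  expect_true("doctors signed" %in% recs$ref)
  expect_equal(recs$hyp[recs$ref == "doctors signed"], "dr san")
  expect_true(any(recs$n_words > 1L))
  # short-word class: reference word shorter than 4 characters
  expect_true(recs$short_word[recs$ref == "in"])
  # flags consistent with ps by construction
  expect_true(all(!recs$homophone | recs$ps == 100))
  expect_true(all(!recs$high_similarity | recs$ps > 75))
  expect_true(all(recs$correction_candidate ==
                    (recs$homophone | recs$high_similarity)))
  # identity pairs never appear as substitutions
  expect_false(any(recs$ref == recs$hyp))
})

test_that("spelling variants and number/abbreviation classes are flagged", {
  al <- align_words(c("johnson", "x", "0", "x", "obs"),
                    c("johnsson", "x", "zero", "x", "observations"))
  recs <- classify_substitutions(al)
  expect_true(recs$spelling_variant_candidate[recs$ref == "johnson"])
  expect_true(recs$number_form[recs$ref == "0"])
  expect_true(recs$abbreviation_expansion[recs$ref == "obs"])
})

test_that("inside-only filtering keeps substitutions at relevant positions", {
  ref <- c("uh", "ken", "harris", "stable")
  hyp <- c("ah", "ken", "harriss", "stable")
  al <- align_words(ref, hyp)
  all_recs <- classify_substitutions(al)
  inside <- classify_substitutions(al, inside_positions = 2:4)
  expect_equal(nrow(all_recs), 2L)
  expect_equal(nrow(inside), 1L)
  expect_equal(inside$ref, "harris")
})

test_that("error profiles count unique errors with set semantics", {
  a1 <- align_words(c("years", "old"), c("yrs", "old"))
  a2 <- align_words(c("years", "young"), c("yrs", "young"))
  recs <- rbind(classify_substitutions(a1), classify_substitutions(a2))
  prof <- error_profile(recs, list(a1, a2))
  expect_equal(prof$unique_substitutions, 1L)  # duplicate pair counted once
  # ten distinct injected pairs -> ten unique substitutions
  # (matched separators keep the units from merging)
  ref <- as.character(rbind(letters[1:10], "sep"))
  hyp <- as.character(rbind(paste0(letters[1:10], "x"), "sep"))
  al <- align_words(ref, hyp)
  prof2 <- error_profile(classify_substitutions(al), list(al))
  expect_equal(prof2$unique_substitutions, 10L)
})

test_that("filler insertions dominate the insertion top list", {
  set.seed(5)
  corpus <- generate_corpus(20, c(30, 80), seed = 5)
  cfg <- corruption_config(substitution_rate = 0, insertion_rate = 0.2,
                           deletion_rate = 0, seed = 5)
  aligns <- lapply(corpus, function(rec) {
    cor <- corrupt_transcript(rec$doc, cfg)
    align_words(token_sequence(rec$doc$tokens), cor$tokens)
  })
  recs <- do.call(rbind, lapply(aligns, classify_substitutions))
  prof <- error_profile(recs, aligns)
  expect_true(all(names(prof$top_insertions) %in%
                    corruption_config()$fillers))
})
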