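box1_written <- paste(
  "Ken harris, bed three, 71 yrs old under Dr Gregor, came in with",
  "arrhythmia. He complained of chest pain this am and ECG was done and was",
  "reviewed by the team. He was given some anginine and morphine for the",
  "pain. Still tachycardic and new meds have been ordered in the medchart.",
  "still for pulse checks for one full minute. Still awaiting echo this",
  "afternoon. His BP is just normal though he is scoring MEWS of 3 for the",
  "tachycardia. He is still for monitoring.")

box1_sr_nursing <- paste(
  "Own now on bed 3 he is then Harry 70 is 71 years old under Dr Greco he",
  "came in with arrhythmia he complained of chest pain this morning in ECG",
  "was done and reviewed by the team he was given some and leaning in",
  "morphine for the pain in she is still tachycardic in new meds have been",
  "ordered in the bedtime is still 4 hours checks for one full minute are",
  "still waiting for echocardiogram this afternoon he is BP is just normal",
  "though he is scarring meals of 3 for the tachycardia larger otherwise he",
  "still for more new taurine.")

test_that("scoring normalization lowercases and strips edge punctuation", {
  expect_equal(as.character(normalize_for_scoring("Ken harris, bed three,")),
               c("ken", "harris", "bed", "three"))
  expect_equal(as.character(normalize_for_scoring("BP is just normal")),
               c("bp", "is", "just", "normal"))
  expect_length(normalize_for_scoring(""), 0L)
  # internal apostrophes/hyphens/decimals retained, digits verbatim
  expect_equal(as.character(normalize_for_scoring("don't re-check 36.8, 0")),
               c("don't", "re-check", "36.8", "0"))
})

test_that("alignment counts satisfy the SCLITE bookkeeping identities", {
  a <- align_words(c("a", "b"), c("a", "b"))
  expect_equal(c(a$C, a$S, a$I, a$D), c(2L, 0L, 0L, 0L))
  expect_equal(a$correctness, 1)
  a <- align_words(c("a", "b"), "a")
  expect_equal(c(a$C, a$D), c(1L, 1L))
  expect_equal(a$correctness, 0.5)
  a <- align_words(character(0), character(0))
  expect_equal(a$correctness, 1)
})

test_that("alignment of the published example pair matches the DP oracle", {
  ref <- normalize_for_scoring(box1_written)
  hyp <- normalize_for_scoring(box1_sr_nursing)
  al <- align_words(ref, hyp)
  expect_equal(al$S + al$I + al$D,
               bf_edit_distance(as.character(ref), as.character(hyp)))
  expect_equal(al$C + al$S + al$D, length(ref))
  expect_equal(al$C + al$S + al$I, length(hyp))
  # the op tally must agree with the counts
  expect_equal(unname(table(al$ops$kind)[c("correct", "substitution",
                                           "insertion", "deletion")]),
               c(al$C, al$S, al$I, al$D), ignore_attr = TRUE)
})

test_that("swapping reference and hypothesis swaps insertions and deletions", {
  set.seed(404)
  for (i in 1:50) {
    r <- sample(letters[1:3], sample(0:6, 1L), replace = TRUE)
    h <- sample(letters[1:3], sample(0:6, 1L), replace = TRUE)
    if (length(r) == 0L || length(h) == 0L) next
    f <- align_words(r, h); b <- align_words(h, r)
    expect_equal(f$C, b$C); expect_equal(f$S, b$S)
    expect_equal(f$I, b$D); expect_equal(f$D, b$I)
  }
})

test_that("correctness ignores case and punctuation of the raw inputs", {
  a1 <- align_words(normalize_for_scoring("He was STABLE today."),
                    normalize_for_scoring("he was stable today"))
  expect_equal(a1$correctness, 1)
})

test_that("corpus summaries pool counts and per-document statistics", {
  expect_error(corpus_correctness(list()), "empty")
  one <- align_words(c("a"), c("a"))
  s <- corpus_correctness(list(one))
  expect_equal(s$mean, 1); expect_equal(s$sd, 0)
  two <- list(align_words(c("a", "b"), c("a", "x")),
              align_words(c("a", "b"), c("a", "b")))
  s <- corpus_correctness(two)
  expect_equal(s$mean, 0.75)
  expect_equal(s$pooled_correct, 3)
  expect_equal(s$total_ref_words, 4)
})

test_that("directory scoring pairs files by stem", {
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  writeLines("the patient is stable", file.path(d1, "r01.txt"))
  writeLines("the patient is stable", file.path(d2, "r01.txt"))
  writeLines("bp was normal", file.path(d1, "r02.txt"))
  writeLines("bp was abnormal", file.path(d2, "r02.txt"))
  res <- score_sr_corpus(d1, d2)
  expect_equal(res$summary$n_documents, 2L)
  expect_equal(res$summary$pooled_correct, 6)
  expect_equal(res$summary$total_ref_words, 7)
})
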