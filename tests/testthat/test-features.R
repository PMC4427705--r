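test_that("the location feature follows the ten-point-scale formula", {
  expect_equal(location_decile(5L, 10L), 5L)
  expect_equal(location_decile(1L, 10L), 1L)
  expect_equal(location_decile(73L, 73L), 10L)
  # formula check against an enumerated mapping
  for (n in c(10L, 37L, 100L)) {
    got <- location_decile(seq_len(n), n)
    expect_equal(got, as.integer(ceiling(10 * seq_len(n) / n)))
    expect_true(all(diff(got) >= 0))            # monotone
    expect_lte(length(unique(got)), 10L)
  }
  # equal blocks when 10 divides n
  blocks <- table(location_decile(seq_len(40L), 40L))
  expect_true(all(blocks == 4L))
  expect_error(location_decile(1L, 0L), "count")
  expect_error(location_decile(11L, 10L), "range")
})

test_that("normalized term frequency is self-normalizing", {
  expect_equal(normalized_tf("a", c("a", "a", "b")), 1)
  expect_equal(normalized_tf("b", c("a", "a", "b")), 0.5)
  expect_equal(normalized_tf("z", c("a", "a", "b")), 0)
  set.seed(9)
  for (i in 1:20) {
    doc <- sample(letters[1:5], 30L, replace = TRUE)
    term <- sample(letters[1:6], 1L)
    expect_equal(normalized_tf(term, doc),
                 sum(doc == term) / max(table(doc)))
  }
})

test_that("medication scores follow the 1 / 0.5 / 0 precedence", {
  lex <- c("acetylsalicylic acid", "morphine", "warfarin sodium")
  expect_equal(medication_score("acetylsalicylic acid", lex), 1)
  expect_equal(medication_score("acetylsalicylic", lex), 0.5)  # sub-part
  expect_equal(medication_score("warfarin sodium tablets", lex), 0.5)
  expect_equal(medication_score("banana", lex), 0)
  expect_equal(medication_score("ACETYLSALICYLIC ACID", lex), 1)  # casefolded
  expect_warning(s <- medication_score("morphine", character(0)), "empty")
  expect_equal(s, 0)
  # the packaged synthetic lexicon contains the canonical example
  expect_equal(medication_score("acetylsalicylic acid",
                                load_medication_lexicon()), 1)
})

test_that("CRF++ files round-trip through the reader/writer", {
  fm1 <- feature_matrix("a", cbind(c("in", "bed", "5"), c("_", "C15", "C15"),
                                   c("50", "15", "15")))
  fm2 <- feature_matrix("b", cbind(c("stable", "today"), c("C24", "_"),
                                   c("24", "50")))
  tf <- tempfile()
  write_crfpp(list(fm1, fm2), tf)
  back <- read_crfpp(tf)
  expect_length(back, 2L)
  expect_identical(back[[1L]]$cells, fm1$cells)
  expect_identical(back[[2L]]$cells, fm2$cells)
  # write(read(x)) is byte-identical
  tf2 <- tempfile()
  write_crfpp(back, tf2)
  expect_identical(readLines(tf), readLines(tf2))
  # randomized round-trip property
  set.seed(31)
  for (i in 1:10) {
    cells <- matrix(sample(c(letters, "_", "0", "42"), 4L * 6L, replace = TRUE),
                    ncol = 4L)
    fm <- feature_matrix("r", cells)
    tfr <- tempfile()
    write_crfpp(fm, tfr)
    expect_identical(read_crfpp(tfr)[[1L]]$cells, fm$cells)
  }
  # empty file -> empty list; ragged rows are parse errors with line numbers
  tfe <- tempfile(); writeLines(character(0), tfe)
  expect_length(read_crfpp(tfe), 0L)
  tfb <- tempfile(); writeLines(c("a\tb\tc", "d\te"), tfb)
  expect_error(read_crfpp(tfb), "line 2")
})

test_that("multi-valued cells are serialized with the fixed separator", {
  expect_equal(join_values(c("bedpan", "blood pressure")), "bedpan|blood_pressure")
  expect_equal(join_values(character(0)), "_")
})

test_that("template expansion produces the seven reference groups", {
  fm <- feature_matrix("d", cbind(c("in", "bed", "5"), c("x", "y", "z"),
                                  c("50", "15", "15")))
  tpl <- default_template(2L)
  ex <- expand_template(tpl, fm, 2L)
  # single-feature-column template on an interior token: 6 unigram groups
  fm1 <- feature_matrix("e", cbind(c("a", "b", "c"), c("1", "2", "3")))
  ex1 <- expand_template(default_template(1L), fm1, 2L)
  expect_length(ex1$uni, 6L)
  expect_setequal(ex1$uni, c("Ua00:b", "Ub00:a", "Uc00:c", "Ud00:a/b",
                             "Ue00:b/c", "Uf00:b"))
  expect_equal(ex1$bi, "B00:b")
  # boundary sentinels at the document edges
  exb <- expand_template(default_template(1L), fm1, 1L)
  expect_true(any(grepl("_B-1", exb$uni)))
  exe <- expand_template(default_template(1L), fm1, 3L)
  expect_true(any(grepl("_B\\+1", exe$uni)))
  # determinism
  expect_identical(expand_template(tpl, fm, 2L), ex)
  # out-of-range column is a template error
  bad <- default_template(3L)
  expect_error(expand_template(bad, fm1, 2L), "template error")
})

test_that("CRF++ template files parse, verify and round-trip", {
  tpl <- default_template(2L)
  tf <- tempfile()
  write_template(tpl, tf)
  back <- read_template(tf)
  expect_true(verify_template(back, 2L))
  fm <- feature_matrix("d", cbind(c("a", "b"), c("1", "2"), c("50", "15")))
  expect_identical(expand_template(back, fm, 1L), expand_template(tpl, fm, 1L))
  # an incomplete template fails verification
  short <- tpl; short$unigrams <- short$unigrams[1:3]
  expect_false(verify_template(short, 2L))
  # bare B macro is a pure transition feature
  tfb <- tempfile(); writeLines(c("U00:%x[0,0]", "B"), tfb)
  bare <- read_template(tfb)
  ex <- expand_template(bare, fm, 2L)
  expect_equal(ex$bi, "B")
})

test_that("the rule provider emits the documented example annotations", {
  ann <- annotate_syntax(c("In", "bed", "5", "we", "have"))
  expect_equal(ann$ner[3L], "number")
  expect_equal(ann$pos[2L], "NN")
  expect_equal(ann$pos[1L], "IN")
  expect_equal(nrow(ann), 5L)
  # provider failure degrades to placeholders with a warning
  boom <- function(tokens) stop("no service")
  expect_warning(out <- annotate_syntax(c("a", "b"), boom), "provider failed")
  expect_equal(out$lemma, c("_", "_"))
})
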