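test_that("segment evaluation handles perfect and degenerate predictions", {
  sch <- load_schema()
  gold <- list(c(7L, 7L, 50L, 24L), c(50L, 32L, 32L))
  perfect <- conll_eval(gold, gold, sch)
  expect_equal(unname(perfect$macro["f1"]), 1)
  expect_equal(unname(perfect$na["f1"]), 1)
  expect_equal(unname(perfect$token_accuracy["correct"]), 7)
  all_na <- lapply(gold, function(g) rep(50L, length(g)))
  worst <- conll_eval(gold, all_na, sch)
  expect_equal(unname(worst$macro["recall"]), 0)
  expect_equal(unname(worst$na["recall"]), 1)
  expect_error(conll_eval(gold, list(c(7L, 7L), c(50L, 32L, 32L)), sch),
               "token count mismatch")
})

test_that("segment counts equal the brute-force segment enumeration", {
  sch <- load_schema()
  set.seed(63)
  for (rep in 1:10) {
    gold <- lapply(1:4, function(i)
      sample(c(50L, sample(sch$id, 4L)), sample(5:20, 1L), replace = TRUE))
    pred <- lapply(gold, function(g) {
      p <- g
      flip <- runif(length(p)) < 0.3
      p[flip] <- sample(sch$id, sum(flip), replace = TRUE)
      p
    })
    r <- conll_eval(gold, pred, sch)
    bf <- bf_segment_counts(gold, pred, sch$id, 50L)
    nonna <- as.character(sch$id[sch$id != 50L])
    expect_equal(r$per_category$tp, unname(bf$tp[nonna]))
    expect_equal(r$per_category$gold_segments, unname(bf$gold[nonna]))
    expect_equal(r$per_category$pred_segments, unname(bf$pred[nonna]))
    # micro F1 lies between the per-category extremes (weighted-mean property)
    act <- r$per_category$gold_segments > 0L
    if (any(act)) {
      expect_lte(round(r$micro_segment["f1"], 10),
                 round(max(r$per_category$f1[act]), 10))
    }
  }
})

test_that("per-category F1 is the harmonic mean of its own P and R", {
  sch <- load_schema()
  gold <- list(c(7L, 50L, 24L, 24L, 50L, 32L))
  pred <- list(c(7L, 24L, 24L, 50L, 50L, 32L))
  r <- conll_eval(gold, pred, sch)
  with(r$per_category, {
    h <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
    expect_equal(f1, h)
  })
})

test_that("confusion matrices conserve tokens and match accuracy", {
  sch <- load_schema()
  gold <- list(c(7L, 7L, 50L), c(24L, 50L))
  pred <- list(c(7L, 8L, 50L), c(24L, 24L))
  cm <- confusion_matrix(gold, pred, sch)
  expect_equal(sum(cm), 5)
  expect_equal(unname(rowSums(cm)[as.character(c(7L))]), 2)
  r <- conll_eval(gold, pred, sch)
  expect_equal(sum(diag(cm)), unname(r$token_accuracy["correct"]))
  ident <- confusion_matrix(gold, gold, sch)
  expect_equal(sum(diag(ident)), sum(ident))
})

test_that("leave-one-out folds exclude exactly the test document", {
  sch <- toy_schema()
  mats <- list(toy_matrix("d1", c("x", "y"), c(1, 2)),
               toy_matrix("d2", c("y", "x"), c(2, 1)),
               toy_matrix("d3", c("x", "x"), c(1, 1)))
  seen <- list()
  trainer <- function(train) {
    seen[[length(seen) + 1L]] <<- vapply(train, `[[`, character(1L), "doc_id")
    majority_baseline(train, sch)
  }
  cv <- loo_cv(mats, sch, trainer = trainer)
  expect_length(seen, 3L)
  expect_equal(seen[[1L]], c("d2", "d3"))
  expect_equal(seen[[3L]], c("d1", "d2"))
  expect_length(cv$predictions, 3L)
  # deterministic given the configuration
  cv2 <- loo_cv(mats, sch, config = crf_config(max_iter = 50L))
  cv3 <- loo_cv(mats, sch, config = crf_config(max_iter = 50L))
  expect_identical(cv2$predictions, cv3$predictions)
})

test_that("leave-one-out recovers labels on a separable synthetic corpus", {
  sc <- shared_corpus()
  cv <- loo_cv(sc$mats, load_schema())
  expect_gte(unname(cv$report$macro["f1"]), 0.9)
  expect_gte(unname(cv$report$na["f1"]), 0.9)
})

test_that("learning curves use a fixed test split and feasible sizes", {
  sc <- shared_corpus()
  lc <- learning_curve(sc$mats, load_schema(), sizes = c(4L, 18L),
                       test_n = 6L, seed = 3L)
  expect_length(lc$test_idx, 6L)
  expect_equal(lc$summary$size, c(4L, 18L))
  # size == all remaining documents uses every remaining document
  expect_equal(nrow(lc$summary), 2L)
  expect_gte(lc$summary$macro_f1[2L], lc$summary$macro_f1[1L] - 0.05)
  expect_error(learning_curve(sc$mats, load_schema(), sizes = 50L,
                              test_n = 6L), "feasible")
})

test_that("ablation collapses a category that depends on one feature", {
  sch <- toy_schema()
  # word column is a constant; only the second feature column separates A/B
  set.seed(41)
  mk <- function(id) {
    lab <- sample(1:2, 8L, replace = TRUE)
    feature_matrix(id, cbind(rep("w", 8L), c("p", "q")[lab], as.character(lab)))
  }
  mats <- lapply(sprintf("d%d", 1:8), mk)
  spec <- feature_spec("cue", 1L)
  expect_error(leave_feature_out(mats, spec, sch), "at least 2")
  spec2 <- feature_spec(c("cue", "cue2"), c(1L, 1L))
  expect_error(leave_feature_out(mats, feature_spec("word", 0L), sch),
               "refused")
  rep <- leave_feature_out(mats, spec2, sch,
                           config = crf_config(max_iter = 60L))
  expect_equal(nrow(rep), 2L)  # one row per dropped type
  expect_gt(rep$macro_f1_delta[1L], 0.3)  # dropping the cue collapses A/B
})

test_that("heading abstraction comparison shares folds and features", {
  sc <- shared_corpus(n = 12L, seed = 19L)
  cmp <- compare_abstraction(sc$mats, load_schema(),
                             config = crf_config(max_iter = 80L))
  expect_equal(cmp$folds, 1:12)
  expect_gte(unname(cmp$fine_then_abstracted$token_accuracy["accuracy"]), 0.9)
  expect_gte(unname(cmp$heading_trained$token_accuracy["accuracy"]), 0.9)
  # the two arms agree within a few points of token accuracy
  expect_lt(abs(cmp$fine_then_abstracted$token_accuracy["accuracy"] -
                cmp$heading_trained$token_accuracy["accuracy"]), 0.05)
})
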