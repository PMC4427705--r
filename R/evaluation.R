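.gold_labels <- function(doc) {
  if (inherits(doc, "annotated_document")) doc$labels
  else if (inherits(doc, "feature_matrix")) fm_labels(doc)
  else as.integer(doc)
}

# Maximal runs of equal labels; returns start/end/label for runs != drop_label.
.segments <- function(labels, drop_label = NA_integer_) {
  r <- rle(labels)
  end <- cumsum(r$lengths); start <- end - r$lengths + 1L
  keep <- if (is.na(drop_label)) rep(TRUE, length(r$values)) else r$values != drop_label
  data.frame(start = start[keep], end = end[keep], label = r$values[keep])
}

.prf <- function(tp, n_pred, n_gold) {
  p <- if (n_pred > 0L) tp / n_pred else 0
  r <- if (n_gold > 0L) tp / n_gold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' CoNLL-style segment evaluation
#'
#' Entities are maximal runs of equal non-NA labels; a predicted segment
#' counts as a true positive only when its boundaries and category match a
#' gold segment exactly. Per-category precision/recall/F1 come from segment
#' counts; macro averages are unweighted means over the categories with
#' nonzero gold support, excluding NA; micro averages pool segment counts
#' over the same categories (a token-level micro average over non-NA tokens
#' is also reported, since it is not stated which granularity a micro average
#' should use). The dominating NA category is scored separately at token
#' granularity (its tallies are conventionally quoted as token counts), and
#' token accuracy (correct tokens / total tokens, NA included) is reported
#' alongside.
#'
#' @param gold List of annotated documents (or feature matrices / label
#'   vectors).
#' @param pred List of predicted label vectors, aligned with `gold`.
#' @param schema The label schema.
#' @return An `eval_report`.
#' @export
conll_eval <- function(gold, pred, schema) {
  if (length(gold) != length(pred)) stop("gold and pred document counts differ")
  gl <- lapply(gold, .gold_labels)
  pl <- lapply(pred, as.integer)
  for (i in seq_along(gl))
    if (length(gl[[i]]) != length(pl[[i]]))
      stop("token count mismatch in document ", i, ": ",
           length(gl[[i]]), " gold vs ", length(pl[[i]]), " predicted")
  na <- na_id(schema)
  cats <- schema$id
  tp <- ng <- np <- stats::setNames(integer(length(cats)), cats)
  for (i in seq_along(gl)) {
    gs <- .segments(gl[[i]], na); ps <- .segments(pl[[i]], na)
    gkey <- paste(gs$start, gs$end, gs$label)
    pkey <- paste(ps$start, ps$end, ps$label)
    hit <- ps[pkey %in% gkey, , drop = FALSE]
    tp <- tp + table(factor(hit$label, levels = cats))
    ng <- ng + table(factor(gs$label, levels = cats))
    np <- np + table(factor(ps$label, levels = cats))
  }
  per <- data.frame(id = cats, name = schema$name,
                    gold_segments = as.integer(ng),
                    pred_segments = as.integer(np), tp = as.integer(tp))
  prf <- t(mapply(.prf, per$tp, per$pred_segments, per$gold_segments))
  per <- cbind(per, prf)
  nonna <- per$id != na
  active <- nonna & per$gold_segments > 0L
  macro <- c(precision = mean(per$precision[active]),
             recall = mean(per$recall[active]),
             f1 = mean(per$f1[active]))
  micro_seg <- .prf(sum(per$tp[active]), sum(per$pred_segments[nonna]),
                    sum(per$gold_segments[nonna]))
  gv <- unlist(gl); pv <- unlist(pl)
  micro_tok <- .prf(sum(gv == pv & gv != na),
                    sum(pv != na), sum(gv != na))
  # NA is the dominating filler category: scored at token granularity, the
  # granularity its tallies are conventionally quoted at
  na_tok <- .prf(sum(gv == pv & gv == na), sum(pv == na), sum(gv == na))
  structure(list(
    per_category = per[nonna, , drop = FALSE],
    macro = macro, micro_segment = micro_seg, micro_token = micro_tok,
    n_macro_categories = sum(active),
    na = c(na_tok, gold_tokens = sum(gv == na)),
    token_accuracy = c(correct = sum(gv == pv), total = length(gv),
                       accuracy = mean(gv == pv))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> macro F1 %.3f (P %.3f, R %.3f) over %d ",
                     "nonempty non-NA categories\n  NA F1 %.3f; token accuracy ",
                     "%d/%d (%.3f)\n"),
              x$macro["f1"], x$macro["precision"], x$macro["recall"],
              x$n_macro_categories, x$na["f1"],
              x$token_accuracy["correct"], x$token_accuracy["total"],
              x$token_accuracy["accuracy"]))
  invisible(x)
}

#' Serialize an evaluation report
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Leave-one-out cross-validation
#'
#' Each document is predicted by a model trained on all the others; metrics
#' are pooled over all documents. The default trainer fits the CRF, with each
#' fold warm-started from the all-document optimum (the penalized likelihood
#' is strictly convex, so the warm start changes only the optimization path,
#' not the fold estimates).
#'
#' @param matrices Annotated `feature_matrix` list (>= 2).
#' @param schema Label schema.
#' @param template Optional `crf_template` (default template otherwise).
#' @param config A [crf_config()].
#' @param trainer Optional `function(train_matrices) -> model`; overrides the
#'   CRF (used for baselines).
#' @param warm_start Warm-start folds from the full-corpus model.
#' @return List with `predictions` (per document), `report` (an
#'   `eval_report`) and `folds`.
#' @export
loo_cv <- function(matrices, schema, template = NULL, config = crf_config(),
                   trainer = NULL, warm_start = TRUE) {
  n <- length(matrices)
  if (n < 2L) stop("leave-one-out needs at least 2 documents")
  preds <- vector("list", n)
  if (!is.null(trainer)) {
    for (i in seq_len(n))
      preds[[i]] <- predict(trainer(matrices[-i]), matrices[[i]])
  } else {
    if (is.null(template))
      template <- default_template(fm_n_feature_cols(matrices[[1L]]))
    L <- nrow(schema)
    feats <- .crf_featurize(matrices, template, schema, cutoff = config$cutoff)
    n_uni <- length(feats$uni_levels); n_bi <- length(feats$bi_levels)
    nw <- n_uni * L + n_bi * L * L
    w_full <- if (warm_start)
      .crf_optim(feats$docs, numeric(nw), L, n_uni, config)$par
    else numeric(nw)
    for (i in seq_len(n)) {
      train_docs <- feats$docs[-i]
      w0 <- .mask_inactive(w_full, train_docs, L, n_uni, n_bi)
      opt <- .crf_optim(train_docs, w0, L, n_uni, config)
      preds[[i]] <- schema$id[.crf_viterbi(feats$docs[[i]], opt$par, L,
                                           n_uni) + 1L]
    }
  }
  list(predictions = preds, report = conll_eval(matrices, preds, schema),
       folds = seq_len(n))
}

#' Learning curve over training-set sizes
#'
#' Samples a fixed test split of `test_n` documents without replacement, then
#' for each requested size samples a training subset from the remaining
#' documents without replacement (independent draw per size under the given
#' seed; when a size equals the whole remainder, all remaining documents are
#' used). Reports one evaluation per size.
#'
#' @param matrices Annotated `feature_matrix` list.
#' @param schema Label schema.
#' @param sizes Training-set sizes.
#' @param test_n Held-out test-set size.
#' @param seed Sampling seed.
#' @param template,config Passed to [train_crf()].
#' @return List with `test_idx`, per-size `reports`, and a `summary` frame.
#' @export
learning_curve <- function(matrices, schema, sizes = c(20L, 40L, 60L, 80L),
                           test_n = 21L, seed = 1L, template = NULL,
                           config = crf_config()) {
  n <- length(matrices)
  pool_n <- n - test_n
  if (test_n >= n || any(sizes > pool_n))
    stop("insufficient documents: with ", n, " documents and test_n = ",
         test_n, ", feasible sizes are 1..", max(0L, pool_n))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  test_idx <- sort(sample.int(n, test_n))
  pool <- setdiff(seq_len(n), test_idx)
  if (is.null(template)) template <- default_template(fm_n_feature_cols(matrices[[1L]]))
  reports <- list()
  for (s in sizes) {
    tr_idx <- if (s == length(pool)) pool else sort(sample(pool, s))
    model <- train_crf(matrices[tr_idx], schema, template, config)
    preds <- predict(model, matrices[test_idx])
    reports[[as.character(s)]] <- conll_eval(matrices[test_idx], preds, schema)
  }
  summary <- data.frame(
    size = sizes,
    macro_f1 = vapply(reports, function(r) unname(r$macro["f1"]), numeric(1L)),
    na_f1 = vapply(reports, function(r) unname(r$na["f1"]), numeric(1L)),
    token_accuracy = vapply(reports, function(r)
      unname(r$token_accuracy["accuracy"]), numeric(1L)))
  list(test_idx = test_idx, reports = reports, summary = summary)
}

#' Leave-feature-out ablation
#'
#' Reruns leave-one-out cross-validation once per feature type with that
#' type's column removed, and reports metric deltas (full system minus
#' ablated system): macro-F1 delta, NA-F1 delta, and the mean per-category F1
#' delta over the attested categories (nonzero gold support, NA included).
#' Dropping the token-surface column is refused.
#'
#' @param matrices Annotated `feature_matrix` list.
#' @param spec A [feature_spec()] naming droppable feature types and their
#'   0-based columns.
#' @param schema,config,warm_start As in [loo_cv()].
#' @return An `ablation_report` data frame (one row per dropped type).
#' @export
leave_feature_out <- function(matrices, spec, schema, config = crf_config(),
                              warm_start = TRUE) {
  if (any(spec$column == 0L))
    stop("dropping the token-surface column is refused")
  if (nrow(spec) < 2L) stop("ablation needs at least 2 active feature types")
  full <- loo_cv(matrices, schema, config = config, warm_start = warm_start)
  fullr <- full$report
  cat_f1 <- function(r) {
    v <- stats::setNames(r$per_category$f1, r$per_category$id)
    c(v, "NA" = unname(r$na["f1"]))
  }
  rows <- lapply(seq_len(nrow(spec)), function(k) {
    col <- spec$column[k]
    reduced <- lapply(matrices, function(fm)
      feature_matrix(fm$doc_id, fm$cells[, -(col + 1L), drop = FALSE],
                     fm$annotated))
    abl <- loo_cv(reduced, schema, config = config, warm_start = warm_start)$report
    attested <- fullr$per_category$gold_segments > 0L
    d_cat <- cat_f1(fullr) - cat_f1(abl)
    data.frame(feature = spec$name[k],
               macro_f1_delta = unname(fullr$macro["f1"] - abl$macro["f1"]),
               na_f1_delta = unname(fullr$na["f1"] - abl$na["f1"]),
               mean_category_delta = mean(c(d_cat[which(attested)],
                                            d_cat["NA"])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_report") <- fullr
  class(out) <- c("ablation_report", "data.frame")
  out
}

#' Token-level confusion matrix
#'
#' Category-by-category token counts with the reference standard in rows and
#' predictions in columns; the diagonal holds correct tokens and row sums
#' equal gold token counts.
#'
#' @param gold,pred Aligned label containers as in [conll_eval()].
#' @param schema Label schema (ids order the rows/columns).
#' @return Integer matrix with category-id dimnames.
#' @export
confusion_matrix <- function(gold, pred, schema) {
  gv <- unlist(lapply(gold, .gold_labels))
  pv <- unlist(lapply(pred, as.integer))
  if (length(gv) != length(pv)) stop("gold/pred token counts differ")
  table(factor(gv, levels = schema$id), factor(pv, levels = schema$id),
        dnn = c("gold", "pred"))
}

#' Compare fine-grained and heading-level training
#'
#' Two systems with identical features, template and leave-one-out folds:
#' the first is trained on the fine-grained (subheading/subsubheading)
#' categories and its predictions abstracted to heading level; the second is
#' trained on heading-level categories directly. Both are evaluated at
#' heading level.
#'
#' @param matrices Annotated fine-grained `feature_matrix` list.
#' @param schema The fine-grained schema.
#' @param template,config,warm_start As in [loo_cv()].
#' @return List with `fine_then_abstracted` and `heading_trained`
#'   (`eval_report`s) and the shared `folds`.
#' @export
compare_abstraction <- function(matrices, schema, template = NULL,
                                config = crf_config(), warm_start = TRUE) {
  hs <- heading_schema(schema)
  fine <- loo_cv(matrices, schema, template, config, warm_start = warm_start)
  abs_preds <- lapply(fine$predictions, heading_of, schema = schema)
  gold_h <- lapply(matrices, function(fm) heading_of(fm_labels(fm), schema))
  rep1 <- conll_eval(gold_h, abs_preds, hs)
  relabeled <- lapply(matrices, function(fm) {
    cells <- fm$cells
    cells[, ncol(cells)] <- as.character(heading_of(fm_labels(fm), schema))
    feature_matrix(fm$doc_id, cells, TRUE)
  })
  head_cv <- loo_cv(relabeled, hs, template, config, warm_start = warm_start)
  stopifnot(identical(fine$folds, head_cv$folds))
  list(fine_then_abstracted = rep1, heading_trained = head_cv$report,
       folds = fine$folds)
}
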