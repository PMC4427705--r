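#' Labeler configuration
#'
#' Hyperparameters of the linear-chain CRF trainer. The reference defaults
#' follow the documented CRF++ defaults: L2 regularization with strength
#' `l2 = 1` (penalty `0.5 * l2 * ||w||^2` added to the negative conditional
#' log-likelihood) and a feature-frequency cut-off of 1 (keep everything).
#' `max_iter` and `factr` control the L-BFGS run (`factr` is the relative
#' convergence tolerance in units of machine epsilon, as in [stats::optim()]).
#'
#' @param l2 L2 penalty strength (> 0).
#' @param max_iter Maximum L-BFGS iterations.
#' @param factr Convergence tolerance factor.
#' @param cutoff Minimum corpus frequency for a feature string to be kept.
#' @param seed Random seed (used by the random baseline only; CRF training is
#'   deterministic).
#' @return A `crf_config` list.
#' @export
crf_config <- function(l2 = 1.0, max_iter = 200L, factr = 1e8, cutoff = 1L,
                       seed = 1L) {
  stopifnot(l2 > 0, max_iter >= 1L, cutoff >= 1L)
  structure(list(l2 = l2, max_iter = as.integer(max_iter), factr = factr,
                 cutoff = as.integer(cutoff), seed = as.integer(seed)),
            class = "crf_config")
}

# Vectorized template expansion over a whole document: one string matrix per
# macro part (tokens x macros).
.expand_doc <- function(fm, template) {
  cells <- fm$cells
  n <- nrow(cells); C <- fm_n_feature_cols(fm)
  padded <- rbind(rep("_B-1", C), cells[, seq_len(C), drop = FALSE],
                  rep("_B+1", C))
  val <- function(off, col) {
    if (col + 1L > C) stop("template error: column index ", col,
                           " out of range (", C, " feature columns)")
    padded[seq_len(n) + 1L + off, col + 1L]
  }
  expand <- function(macros) {
    out <- matrix("", n, length(macros))
    for (j in seq_along(macros)) {
      m <- macros[[j]]; nm <- names(macros)[j]
      if (nrow(m) == 0L) { out[, j] <- nm; next }
      pieces <- lapply(seq_len(nrow(m)),
                       function(i) val(m[i, "offset"], m[i, "col"]))
      out[, j] <- paste0(nm, ":", do.call(paste, c(pieces, sep = "/")))
    }
    out
  }
  list(uni = expand(template$unigrams), bi = expand(template$bigrams))
}

.csr <- function(strmat, levels) {
  n <- nrow(strmat)
  idxm <- matrix(match(strmat, levels), nrow = n)
  tv <- as.vector(t(idxm))
  keep <- !is.na(tv)
  counts <- ncol(strmat) - rowSums(is.na(idxm))
  list(ptr = c(0L, cumsum(as.integer(counts))), idx = as.integer(tv[keep] - 1L))
}

.crf_featurize <- function(matrices, template, schema,
                           uni_levels = NULL, bi_levels = NULL, cutoff = 1L) {
  ex <- lapply(matrices, .expand_doc, template = template)
  build_levels <- function(part) {
    all <- unlist(lapply(ex, `[[`, part), use.names = FALSE)
    lev <- unique(all)
    if (cutoff > 1L) {
      cnt <- tabulate(match(all, lev), nbins = length(lev))
      lev <- lev[cnt >= cutoff]
    }
    lev
  }
  if (is.null(uni_levels)) uni_levels <- build_levels("uni")
  if (is.null(bi_levels)) bi_levels <- build_levels("bi")
  docs <- vector("list", length(matrices))
  for (i in seq_along(matrices)) {
    fm <- matrices[[i]]
    u <- .csr(ex[[i]]$uni, uni_levels)
    b <- .csr(ex[[i]]$bi, bi_levels)
    y <- if (fm$annotated) {
      lab <- match(fm_labels(fm), schema$id)
      if (anyNA(lab)) stop("document ", fm$doc_id, " carries label(s) not in schema")
      as.integer(lab - 1L)
    } else integer(nrow(fm$cells))
    docs[[i]] <- list(uptr = u$ptr, uidx = u$idx,
                      bptr = b$ptr, bidx = b$idx, y = y)
  }
  list(docs = docs, uni_levels = uni_levels, bi_levels = bi_levels)
}

.crf_optim <- function(docs, w0, L, n_uni, config) {
  cache <- new.env(parent = emptyenv())
  evaluate <- function(w) {
    if (!is.null(cache$w) && identical(cache$w, w)) return(invisible(NULL))
    res <- .crf_nll_grad(docs, w, L, n_uni, config$l2, TRUE)
    cache$w <- w; cache$nll <- res$nll; cache$grad <- res$grad
    invisible(NULL)
  }
  fn <- function(w) { evaluate(w); cache$nll }
  gr <- function(w) { evaluate(w); cache$grad }
  stats::optim(w0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = config$max_iter, factr = config$factr))
}

# Zero the weight blocks of features absent from a training subset: at the
# subset optimum those weights are exactly zero (penalty only), so a warm
# start must not carry them over.
.mask_inactive <- function(w, docs, L, n_uni, n_bi) {
  act_u <- unique(unlist(lapply(docs, `[[`, "uidx")))
  act_b <- unique(unlist(lapply(docs, `[[`, "bidx")))
  inact_u <- setdiff(seq_len(n_uni) - 1L, act_u)
  inact_b <- setdiff(seq_len(n_bi) - 1L, act_b)
  if (length(inact_u))
    w[rep(inact_u * L, each = L) + seq_len(L)] <- 0
  if (length(inact_b))
    w[n_uni * L + rep(inact_b * L * L, each = L * L) + seq_len(L * L)] <- 0
  w
}

#' Train a linear-chain CRF token classifier
#'
#' Fits feature weights by maximizing the L2-penalized conditional
#' log-likelihood of the label sequences given the expanded template features,
#' with exact forward-backward gradients and L-BFGS optimization. Unigram
#' features couple a feature string with the current label; bigram features
#' couple a feature string with the (previous label, current label) pair.
#' Training is deterministic given inputs and configuration.
#'
#' @param matrices Annotated `feature_matrix` list (>= 1 document).
#' @param schema The `handover_schema` defining the label set.
#' @param template A `crf_template`; defaults to [default_template()] over the
#'   feature columns of the first document.
#' @param config A [crf_config()].
#' @param init Optional initial weight vector (warm start); defaults to zero.
#' @return A `crf_model`.
#' @export
train_crf <- function(matrices, schema, template = NULL,
                      config = crf_config(), init = NULL) {
  if (length(matrices) < 1L) stop("training requires at least one document")
  if (is.null(template)) template <- default_template(fm_n_feature_cols(matrices[[1L]]))
  L <- nrow(schema)
  feats <- .crf_featurize(matrices, template, schema, cutoff = config$cutoff)
  n_uni <- length(feats$uni_levels); n_bi <- length(feats$bi_levels)
  nw <- n_uni * L + n_bi * L * L
  w0 <- if (is.null(init)) numeric(nw) else {
    stopifnot(length(init) == nw); init
  }
  opt <- .crf_optim(feats$docs, w0, L, n_uni, config)
  structure(list(weights = opt$par, uni_levels = feats$uni_levels,
                 bi_levels = feats$bi_levels, template = template,
                 schema = schema, config = config, L = L,
                 nll = opt$value, convergence = opt$convergence,
                 n_train_docs = length(matrices)),
            class = "crf_model")
}

#' Penalized negative log-likelihood of a corpus under a model
#'
#' @param model A `crf_model`.
#' @param matrices Annotated `feature_matrix` list.
#' @param weights Optional weight vector to evaluate instead of the model's.
#' @return The penalized negative conditional log-likelihood.
#' @export
crf_objective <- function(model, matrices, weights = model$weights) {
  feats <- .crf_featurize(matrices, model$template, model$schema,
                          uni_levels = model$uni_levels,
                          bi_levels = model$bi_levels)
  .crf_nll_grad(feats$docs, weights, model$L, length(model$uni_levels),
                model$config$l2, FALSE)$nll
}

#' Predict label sequences
#'
#' Viterbi decoding: exactly one category per token. Feature strings unseen
#' in training carry no weight and are ignored, so prediction is total (an
#' all-unknown document still receives labels).
#'
#' @param object A `crf_model`.
#' @param newdata A `feature_matrix` or list of them.
#' @param ... Unused.
#' @return Integer label vector (single document) or list of them.
#' @export
predict.crf_model <- function(object, newdata, ...) {
  single <- inherits(newdata, "feature_matrix")
  if (single) newdata <- list(newdata)
  feats <- .crf_featurize(newdata, object$template, object$schema,
                          uni_levels = object$uni_levels,
                          bi_levels = object$bi_levels)
  out <- lapply(feats$docs, function(d)
    object$schema$id[.crf_viterbi(d, object$weights, object$L,
                                  length(object$uni_levels)) + 1L])
  if (single) out[[1L]] else out
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf(paste0("<crf_model> %d labels, %d unigram + %d bigram feature ",
                     "strings (%d weights)\n  trained on %d document(s), ",
                     "penalized NLL %.3f\n"),
              x$L, length(x$uni_levels), length(x$bi_levels),
              length(x$weights), x$n_train_docs, x$nll))
  invisible(x)
}

# ---- model serialization ----------------------------------------------------

#' Save / load a CRF model as a self-describing text file
#'
#' Versioned single-file JSON format holding the label schema, template,
#' feature dictionaries and weights.
#'
#' @param model A `crf_model`.
#' @param path File path.
#' @export
save_crf_model <- function(model, path) {
  tpl <- lapply(model$template, function(part)
    lapply(part, function(m) list(offset = unname(m[, "offset"]),
                                  col = unname(m[, "col"]))))
  obj <- list(format = "handoverNLP-crf", version = 1L,
              schema = as.data.frame(model$schema),
              schema_level = attr(model$schema, "level"),
              template = tpl,
              uni_levels = model$uni_levels, bi_levels = model$bi_levels,
              config = unclass(model$config), L = model$L, nll = model$nll,
              n_train_docs = model$n_train_docs, weights = model$weights)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_crf_model
#' @export
load_crf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "handoverNLP-crf"))
    stop("not a handoverNLP CRF model file: ", path)
  rebuild <- function(part) lapply(part, function(m)
    cbind(offset = as.integer(m$offset), col = as.integer(m$col)))
  template <- structure(list(unigrams = rebuild(obj$template$unigrams),
                             bigrams = rebuild(obj$template$bigrams)),
                        class = "crf_template")
  schema <- .make_schema(obj$schema, level = obj$schema_level)
  structure(list(weights = as.numeric(obj$weights),
                 uni_levels = as.character(obj$uni_levels),
                 bi_levels = as.character(obj$bi_levels),
                 template = template, schema = schema,
                 config = do.call(crf_config, obj$config),
                 L = as.integer(obj$L), nll = obj$nll,
                 convergence = 0L, n_train_docs = obj$n_train_docs),
            class = "crf_model")
}

# ---- baselines --------------------------------------------------------------

#' Majority and random baseline labelers
#'
#' The majority baseline labels every token with the most frequent non-NA
#' training label; the random baseline assigns each token a category drawn
#' uniformly over all schema categories under a fixed seed (reproducible per
#' document).
#'
#' @param matrices Annotated training `feature_matrix` list.
#' @param schema The label schema.
#' @return A `baseline_model`.
#' @export
majority_baseline <- function(matrices, schema) {
  labs <- unlist(lapply(matrices, fm_labels))
  labs <- labs[labs != na_id(schema)]
  if (length(labs) == 0L) labs <- na_id(schema)
  tab <- table(factor(labs, levels = schema$id))
  structure(list(kind = "majority",
                 label = schema$id[which.max(tab)], schema = schema),
            class = "baseline_model")
}

#' @rdname majority_baseline
#' @param seed Integer seed for the random baseline.
#' @export
random_baseline <- function(schema, seed = 1L) {
  structure(list(kind = "random", seed = as.integer(seed), schema = schema),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  single <- inherits(newdata, "feature_matrix")
  if (single) newdata <- list(newdata)
  out <- lapply(newdata, function(fm) {
    n <- nrow(fm$cells)
    if (object$kind == "majority") return(rep(object$label, n))
    h <- (sum(utf8ToInt(paste(fm_tokens(fm), collapse = ""))) + n) %% 1000003L
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed((object$seed * 2654435L + h) %% 2147483647L)
    sample(object$schema$id, n, replace = TRUE)
  })
  if (single) out[[1L]] else out
}
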