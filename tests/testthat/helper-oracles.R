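# Independent oracles used by the tests. These deliberately avoid the code
# paths of the package implementation (no utils::adist, no rle-based segment
# extraction, no forward-backward).

# Plain dynamic-programming minimum edit distance over token vectors.
bf_edit_distance <- function(a, b) {
  na <- length(a); nb <- length(b)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1L)
    cur[1L] <- i
    for (j in seq_len(nb)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j] + cost, prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[nb + 1L]
}

# Loop-based segment scorer: finds maximal same-label runs by explicit
# boundary scanning and tallies exact matches per category.
bf_segment_counts <- function(gold, pred, ids, na) {
  find_segments <- function(lab) {
    segs <- list()
    t <- 1L; n <- length(lab)
    while (t <= n) {
      if (lab[t] != na) {
        e <- t
        while (e < n && lab[e + 1L] == lab[t]) e <- e + 1L
        segs[[length(segs) + 1L]] <- c(start = t, end = e, label = lab[t])
        t <- e + 1L
      } else t <- t + 1L
    }
    segs
  }
  tp <- ng <- np <- stats::setNames(integer(length(ids)), ids)
  for (i in seq_along(gold)) {
    gs <- find_segments(gold[[i]]); ps <- find_segments(pred[[i]])
    for (s in gs) ng[as.character(s["label"])] <- ng[as.character(s["label"])] + 1L
    for (s in ps) {
      k <- as.character(s["label"])
      np[k] <- np[k] + 1L
      hit <- any(vapply(gs, function(g) all(g == s), logical(1L)))
      if (hit) tp[k] <- tp[k] + 1L
    }
  }
  list(tp = tp, gold = ng, pred = np)
}

# Exhaustive log-partition-function and best path by enumerating every label
# sequence of a (tiny) featurized document.
bf_crf_enumerate <- function(doc, w, L, n_uni) {
  T <- length(doc$y)
  score_seq <- function(y) {  # y is 0-based
    s <- 0
    for (t in seq_len(T)) {
      js <- seq.int(doc$uptr[t] + 1L, length.out = doc$uptr[t + 1L] - doc$uptr[t])
      for (j in js) s <- s + w[doc$uidx[j] * L + y[t] + 1L]
    }
    if (T > 1L) for (t in 2:T) {
      js <- seq.int(doc$bptr[t] + 1L, length.out = doc$bptr[t + 1L] - doc$bptr[t])
      for (j in js) s <- s + w[n_uni * L + doc$bidx[j] * L * L + y[t - 1L] * L + y[t] + 1L]
    }
    s
  }
  grid <- as.matrix(do.call(expand.grid, rep(list(0:(L - 1L)), T)))
  sc <- apply(grid, 1L, score_seq)
  list(logZ = log(sum(exp(sc))), best = as.integer(grid[which.max(sc), ]),
       gold_score = score_seq(doc$y))
}

# A minimal 3-category schema (two content categories plus NA) for toy CRFs.
toy_schema <- function() {
  df <- data.frame(id = 1:3, heading = c("A", "B", "NA"),
                   subheading = "", subsubheading = "",
                   stringsAsFactors = FALSE)
  handoverNLP:::.make_schema(df, level = "heading")
}

toy_matrix <- function(id, tokens, labels) {
  feature_matrix(id, cbind(tokens, as.character(labels)), annotated = TRUE)
}

# Shared medium corpus for CRF/evaluation tests (built once per test run).
shared_corpus_env <- new.env()
shared_corpus <- function(n = 24L, seed = 11L) {
  key <- paste0("c", n, "_", seed)
  if (is.null(shared_corpus_env[[key]])) {
    corpus <- generate_corpus(n, c(30L, 90L), seed = seed)
    shared_corpus_env[[key]] <- list(corpus = corpus,
                                     mats = corpus_features(corpus))
  }
  shared_corpus_env[[key]]
}
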