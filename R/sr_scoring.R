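#' Normalize raw text for word-alignment scoring
#'
#' Scoring ignores punctuation and capitalization: the text is whitespace
#' tokenized, lowercased, and leading/trailing punctuation is stripped from
#' each token. Word-internal apostrophes, hyphens and decimal points are
#' retained, and digit strings are kept verbatim (no digit/word folding, so
#' "0" vs "zero" stays a scoring error).
#'
#' @param text A raw document string (or vector of lines).
#' @param source_id Identifier recorded on the sequence.
#' @return A `token_sequence`: character vector of tokens with attributes.
#' @examples
#' normalize_for_scoring("Ken harris, bed three,")  # ken harris bed three
#' @export
normalize_for_scoring <- function(text, source_id = "") {
  raw <- unlist(strsplit(tolower(paste(text, collapse = " ")), "[[:space:]]+"))
  toks <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", raw)
  toks <- toks[nzchar(toks)]
  token_sequence(toks, source_id)
}

#' Construct a token sequence
#' @param tokens Character vector of normalized tokens (no empty tokens).
#' @param source_id Identifier string.
#' @return A `token_sequence`.
#' @export
token_sequence <- function(tokens, source_id = "") {
  tokens <- as.character(tokens)
  if (any(!nzchar(tokens))) stop("token_sequence: empty tokens are not allowed")
  structure(tokens, source_id = as.character(source_id),
            class = c("token_sequence", "character"))
}

.seq_tokens <- function(x) {
  if (inherits(x, "token_sequence")) as.character(unclass(x)) else as.character(x)
}

#' Minimum-edit word alignment of reference and hypothesis
#'
#' SCLITE-style alignment: a minimum-cost edit script between the reference
#' and hypothesis token sequences under unit substitution/insertion/deletion
#' cost and zero match cost, yielding counts of correct (C), substituted (S),
#' inserted (I) and deleted (D) words and the word correctness C/|ref|.
#' Among equal-cost alignments the one maximizing matched words is taken, so
#' the counts are canonical: C+S+D = |ref|, C+S+I = |hyp|, and swapping
#' reference and hypothesis exchanges I and D while preserving C and S. Op
#' ordering among residual ties is not contract-bearing, the counts are.
#'
#' @param ref,hyp Token sequences (see [normalize_for_scoring()]) or plain
#'   character vectors of already-normalized tokens.
#' @return An `alignment_result`: list with `ops` (data frame of
#'   kind/ref_token/hyp_token), counts `C`, `S`, `I`, `D`, and `correctness`.
#' @export
align_words <- function(ref, hyp) {
  r <- .seq_tokens(ref); h <- .seq_tokens(hyp)
  ops_chr <- strsplit(.word_align(r, h), "")[[1L]]
  ri <- 0L; hi <- 0L
  kind <- character(length(ops_chr))
  rt <- character(length(ops_chr)); ht <- character(length(ops_chr))
  for (k in seq_along(ops_chr)) {
    op <- ops_chr[k]
    if (op == "M") { ri <- ri + 1L; hi <- hi + 1L
      kind[k] <- "correct"; rt[k] <- r[ri]; ht[k] <- h[hi]
    } else if (op == "S") { ri <- ri + 1L; hi <- hi + 1L
      kind[k] <- "substitution"; rt[k] <- r[ri]; ht[k] <- h[hi]
    } else if (op == "I") { hi <- hi + 1L
      kind[k] <- "insertion"; rt[k] <- NA_character_; ht[k] <- h[hi]
    } else { ri <- ri + 1L
      kind[k] <- "deletion"; rt[k] <- r[ri]; ht[k] <- NA_character_ }
  }
  ops <- data.frame(kind = kind, ref_token = rt, hyp_token = ht,
                    stringsAsFactors = FALSE)
  C <- sum(kind == "correct"); S <- sum(kind == "substitution")
  I <- sum(kind == "insertion"); D <- sum(kind == "deletion")
  correctness <- if (length(r) == 0L) as.numeric(length(h) == 0L) else C / length(r)
  structure(list(ops = ops, C = C, S = S, I = I, D = D,
                 n_ref = length(r), n_hyp = length(h),
                 correctness = correctness,
                 ref_id = attr(ref, "source_id") %||% "",
                 hyp_id = attr(hyp, "source_id") %||% ""),
            class = "alignment_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> C=%d S=%d I=%d D=%d correctness=%.3f\n",
              x$C, x$S, x$I, x$D, x$correctness))
  invisible(x)
}

#' Corpus-level word-correctness summary
#'
#' Per-document statistics (mean, SD, minimum, maximum, median of word
#' correctness) together with pooled counts: total correct words, total
#' reference words, and the pooled ratio.
#'
#' @param results A list of `alignment_result` objects (at least one).
#' @return An `sr_summary` list.
#' @export
corpus_correctness <- function(results) {
  if (length(results) < 1L) stop("corpus_correctness: empty result list")
  if (inherits(results, "alignment_result")) results <- list(results)
  corr <- vapply(results, function(a) a$correctness, numeric(1L))
  pooled_C <- sum(vapply(results, function(a) a$C, numeric(1L)))
  total_ref <- sum(vapply(results, function(a) a$n_ref, numeric(1L)))
  structure(list(
    n_documents = length(results),
    mean = mean(corr), sd = if (length(corr) > 1L) stats::sd(corr) else 0,
    min = min(corr), max = max(corr), median = stats::median(corr),
    pooled_correct = pooled_C, total_ref_words = total_ref,
    pooled_correctness = if (total_ref > 0) pooled_C / total_ref else NA_real_,
    per_document = data.frame(
      doc = vapply(results, function(a) a$ref_id, character(1L)),
      C = vapply(results, function(a) a$C, numeric(1L)),
      S = vapply(results, function(a) a$S, numeric(1L)),
      I = vapply(results, function(a) a$I, numeric(1L)),
      D = vapply(results, function(a) a$D, numeric(1L)),
      n_ref = vapply(results, function(a) a$n_ref, numeric(1L)),
      correctness = corr, stringsAsFactors = FALSE)),
    class = "sr_summary")
}

#' @export
print.sr_summary <- function(x, ...) {
  cat(sprintf(paste0("<sr_summary> %d documents\n",
                     "  word correctness: mean %.3f (SD %.3f), min %.3f, ",
                     "median %.3f, max %.3f\n",
                     "  pooled: %d/%d correct words (%.3f)\n"),
              x$n_documents, x$mean, x$sd, x$min, x$median, x$max,
              x$pooled_correct, x$total_ref_words, x$pooled_correctness))
  invisible(x)
}

#' Score a reference directory against a hypothesis directory
#'
#' Reads plain-text documents (one document per `.txt` file), pairs reference
#' and hypothesis files by filename stem, normalizes both sides, aligns each
#' pair and summarizes word correctness over the corpus.
#'
#' @param ref_dir Directory of reference text files.
#' @param hyp_dir Directory of speech-recognized hypothesis text files.
#' @return List with `alignments` (per document) and `summary` (`sr_summary`).
#' @export
score_sr_corpus <- function(ref_dir, hyp_dir) {
  rf <- list.files(ref_dir, pattern = "\\.txt$", full.names = TRUE)
  hf <- list.files(hyp_dir, pattern = "\\.txt$", full.names = TRUE)
  rstem <- tools::file_path_sans_ext(basename(rf))
  hstem <- tools::file_path_sans_ext(basename(hf))
  common <- intersect(rstem, hstem)
  if (length(common) == 0L) stop("no filename stems shared between ref and hyp")
  aligns <- lapply(common, function(s) {
    ref <- normalize_for_scoring(readLines(rf[match(s, rstem)], warn = FALSE), s)
    hyp <- normalize_for_scoring(readLines(hf[match(s, hstem)], warn = FALSE), s)
    align_words(ref, hyp)
  })
  names(aligns) <- common
  list(alignments = aligns, summary = corpus_correctness(aligns))
}
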