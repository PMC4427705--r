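#' Ten-point document-location feature
#'
#' Position of a word on a ten-point scale from the beginning of the document
#' to its end: `ceiling(10 * index / n)`, so the first word maps to 1 and the
#' last word to 10. Monotone non-decreasing in `index`.
#'
#' @param index 1-based token position (vectorized).
#' @param n Document token count.
#' @return Integer decile(s) in 1..10.
#' @export
location_decile <- function(index, n) {
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("location_decile: document token count must be >= 1")
  index <- as.integer(index)
  if (any(index < 1L | index > n)) stop("location_decile: index out of range")
  as.integer(ceiling(10 * index / n))
}

#' Normalized term frequency
#'
#' Number of times a term occurs in the document divided by the maximum term
#' frequency over all terms of the document. The most frequent term scores 1;
#' a term absent from the document scores 0 by convention.
#'
#' @param term A word.
#' @param tokens Character vector of document tokens.
#' @return Fraction in \[0, 1\].
#' @export
normalized_tf <- function(term, tokens) {
  if (length(tokens) == 0L) return(0)
  tab <- table(tokens)
  cnt <- tab[term]
  if (is.na(cnt)) return(0)
  as.numeric(cnt) / max(tab)
}

#' Load a medication-ingredient lexicon
#'
#' Plain-text term list (one ingredient term per line, `#` comments ignored),
#' standing in for the Anatomical Therapeutic Chemical (ATC) ingredient list.
#' The packaged default is a synthetic stand-in.
#'
#' @param path Lexicon file path; defaults to the packaged synthetic list.
#' @return Lowercased character vector of terms.
#' @export
load_medication_lexicon <- function(path = system.file(
    "extdata", "atc_ingredients_synthetic.txt", package = "handoverNLP")) {
  lines <- trimws(readLines(path, warn = FALSE))
  tolower(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Medication score of a phrase against an ingredient lexicon
#'
#' Returns 1 when the phrase is a full lexicon term, 0.5 when it can be found
#' in the lexicon as a strict sub-part of some term (or a lexicon term occurs
#' within the phrase), and 0 otherwise. Matching is case-insensitive, at word
#' boundaries, with strict precedence 1 > 0.5 > 0.
#'
#' @param phrase A word or word sequence (character vector or single string).
#' @param lexicon Character vector of ingredient terms (see
#'   [load_medication_lexicon()]).
#' @return One of 1, 0.5, 0.
#' @export
medication_score <- function(phrase, lexicon) {
  if (length(lexicon) == 0L) {
    warning("empty medication lexicon: all scores are 0")
    return(0)
  }
  lexicon <- tolower(trimws(lexicon))
  p <- tolower(trimws(paste(phrase, collapse = " ")))
  if (!nzchar(p)) return(0)
  if (p %in% lexicon) return(1)
  pat <- paste0("\\b", .regex_escape(p), "\\b")
  if (any(grepl(pat, lexicon, perl = TRUE))) return(0.5)
  inner <- vapply(lexicon, function(term)
    grepl(paste0("\\b", .regex_escape(term), "\\b"), p, perl = TRUE),
    logical(1L))
  if (any(inner)) return(0.5)
  0
}

.regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# ---- syntactic/semantic annotation providers --------------------------------

.irregular_lemmas <- c(is = "be", was = "be", are = "be", been = "be",
                       am = "be", were = "be", came = "come", has = "have",
                       had = "have", given = "give", done = "do")
.preps <- c("in", "on", "at", "for", "with", "under", "of", "to", "by", "from")
.prons <- c("he", "she", "we", "i", "his", "her", "they", "you", "it")
.dets  <- c("the", "a", "an", "this", "that", "some", "any")
.verbs <- c("is", "was", "are", "am", "were", "came", "come", "have", "has",
            "been", "be", "given", "needs", "complained", "scoring", "awaiting",
            "ordered", "reviewed", "done", "draining", "planned", "booked")
.months <- c("january", "february", "march", "april", "may", "june", "july",
             "august", "september", "october", "november", "december",
             "jan", "feb", "mar", "apr", "jun", "jul", "aug", "sep", "oct",
             "nov", "dec")

#' A simple deterministic rule-based annotation provider
#'
#' Providers supply the syntactic/semantic feature columns (lemma,
#' part-of-speech, named-entity tag, root-to-word parse path, basic
#' dependents/governors, containing phrase, concept candidates, top concept
#' mapping) for [annotate_syntax()]. The rule provider is a small
#' deterministic annotator: suffix/table lemmatization, regex and word-list
#' part-of-speech and named-entity tagging, and window-based
#' dependent/governor/phrase columns. It exists so the pipeline runs without
#' external annotators; precomputed columns from a full NLP stack can be
#' ingested instead via [read_crfpp()].
#'
#' @return A provider function: `function(tokens) -> data.frame`.
#' @export
rule_provider <- function() {
  function(tokens) {
    low <- tolower(tokens)
    lemma <- ifelse(low %in% names(.irregular_lemmas),
                    unname(.irregular_lemmas[match(low, names(.irregular_lemmas))]),
                    ifelse(nchar(low) > 3L & endsWith(low, "s") & !endsWith(low, "ss"),
                           substr(low, 1L, nchar(low) - 1L), low))
    pos <- ifelse(grepl("^[0-9]+([./:][0-9]+)?$", low), "CD",
           ifelse(low %in% .preps, "IN",
           ifelse(low %in% .prons, "PRP",
           ifelse(low %in% .dets, "DT",
           ifelse(low %in% .verbs, "VB", "NN")))))
    ner <- ifelse(grepl("^[0-9]+([./:][0-9]+)?$", low), "number",
           ifelse(low %in% .months, "date", "O"))
    n <- length(tokens)
    prv <- c("_B-1", low[-n]); nxt <- c(low[-1L], "_B+1")
    data.frame(lemma = lemma, pos = pos, ner = ner,
               parse = paste0("ROOT-", pos),
               dependents = nxt, governors = prv,
               phrase = paste(prv, low, nxt, sep = "_"),
               candidates = "_", mapping = "_",
               stringsAsFactors = FALSE)
  }
}

#' Annotate tokens with syntactic/semantic feature columns
#'
#' Runs a provider over the tokens and returns one value per token per
#' feature; multi-valued outputs must already be serialized with
#' [join_values()]. A provider failure for a token yields the placeholder
#' `"_"` and a warning.
#'
#' @param tokens Character vector of document tokens.
#' @param provider A provider function (default [rule_provider()]).
#' @return Data frame of feature columns, one row per token.
#' @export
annotate_syntax <- function(tokens, provider = rule_provider()) {
  out <- tryCatch(provider(tokens), error = function(e) {
    warning("annotation provider failed: ", conditionMessage(e),
            "; emitting placeholders")
    NULL
  })
  if (is.null(out))
    out <- data.frame(lemma = rep("_", length(tokens)), pos = "_", ner = "_",
                      parse = "_", dependents = "_", governors = "_",
                      phrase = "_", candidates = "_", mapping = "_",
                      stringsAsFactors = FALSE)
  if (nrow(out) != length(tokens))
    stop("provider returned ", nrow(out), " rows for ", length(tokens), " tokens")
  out[is.na(out)] <- "_"
  out
}

#' Feature-type specification
#'
#' Maps named feature types to the columns of a feature matrix. Used by the
#' ablation driver to drop one feature type at a time; the token-surface
#' column can never be dropped.
#'
#' @param names Character vector of feature-type names.
#' @param columns Integer vector of 0-based column indices (parallel to
#'   `names`); column 0 is the token surface.
#' @return A `feature_spec` data frame.
#' @export
feature_spec <- function(names, columns) {
  stopifnot(length(names) == length(columns))
  structure(data.frame(name = names, column = as.integer(columns),
                       stringsAsFactors = FALSE),
            class = c("feature_spec", "data.frame"))
}
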