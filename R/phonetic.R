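#' Phonetic similarity between word sequences
#'
#' Each word is Double Metaphone encoded, per-word codes are concatenated in
#' order, and the phonetic similarity (PS) percentage is
#' `100 * (1 - editdist(ref_code, hyp_code) / max(nchar(ref_code), nchar(hyp_code)))`
#' under unweighted (unit-cost) edit distance. When primary codes differ, the
#' maximum similarity over primary/alternate code combinations is taken
#' (accent tolerance is the reason for using Double Metaphone). PS = 100
#' means the sequences sound exactly alike (homophones, e.g. "four" vs
#' "for"). Degenerate all-vowel/digit words encode to empty codes; if both
#' codes are empty, PS is 100 when the lowercased sequences are equal and 0
#' otherwise.
#'
#' @param ref_seq,hyp_seq Non-empty character vectors of words.
#' @return A `phonetic_match`: list with `ref_seq`, `hyp_seq`, `ref_code`,
#'   `hyp_code` (primary codes) and `ps` in \[0, 100\].
#' @examples
#' phonetic_similarity("four", "for")$ps  # 100
#' @export
phonetic_similarity <- function(ref_seq, hyp_seq) {
  if (length(ref_seq) < 1L || length(hyp_seq) < 1L)
    stop("phonetic_similarity: both sequences must be non-empty")
  rp <- encode_sequence(ref_seq); hp <- encode_sequence(hyp_seq)
  if (!nzchar(rp) && !nzchar(hp)) {
    ps <- if (identical(tolower(paste(ref_seq, collapse = " ")),
                        tolower(paste(hyp_seq, collapse = " ")))) 100 else 0
  } else {
    ps <- .code_similarity(rp, hp)
    if (ps < 100) {
      ra <- encode_sequence(ref_seq, alternate = TRUE)
      ha <- encode_sequence(hyp_seq, alternate = TRUE)
      ps <- max(ps, .code_similarity(rp, ha), .code_similarity(ra, hp),
                .code_similarity(ra, ha), na.rm = TRUE)
    }
  }
  structure(list(ref_seq = ref_seq, hyp_seq = hyp_seq,
                 ref_code = rp, hyp_code = hp, ps = ps),
            class = "phonetic_match")
}

.code_similarity <- function(a, b) {
  if (!nzchar(a) && !nzchar(b)) return(NA_real_)  # degenerate; caller decides
  if (!nzchar(a) || !nzchar(b)) return(0)
  100 * (1 - as.numeric(utils::adist(a, b)) / max(nchar(a), nchar(b)))
}

.default_number_lexicon <- c(
  "zero", "one", "two", "three", "four", "five", "six", "seven", "eight",
  "nine", "ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen",
  "sixteen", "seventeen", "eighteen", "nineteen", "twenty")

.default_abbreviations <- data.frame(
  short = c("am", "obs", "k", "yrs", "dr", "bp", "echo", "meds"),
  long  = c("this morning", "observations", "potassium", "years", "doctor",
            "blood pressure", "echocardiogram", "medications"),
  stringsAsFactors = FALSE)

#' Classify substitution errors by phonetic similarity
#'
#' Builds one record per substitution unit of a word alignment, where maximal
#' runs of adjacent substitution ops are merged into a single multi-word unit
#' (e.g. "doctors signed" vs "dr san"). Each record carries the PS percentage
#' and error-class flags:
#' \describe{
#'   \item{homophone}{PS = 100 — sounds exactly like the reference.}
#'   \item{high_similarity}{PS > 75.}
#'   \item{short_word}{every reference word shorter than 4 characters.}
#'   \item{spelling_variant_candidate}{surface edit distance 1 with PS = 100
#'     (e.g. "Johnson" vs "Johnsson").}
#'   \item{number_form}{a side matches the number lexicon (digits or number
#'     words), e.g. "0" vs "zero".}
#'   \item{abbreviation_expansion}{a side matches the abbreviation table
#'     (e.g. "obs" vs "observations").}
#' }
#' A record is a correction candidate when it is a homophone or has PS > 75.
#'
#' @param alignment An `alignment_result` from [align_words()].
#' @param inside_positions Optional integer vector of 1-based reference token
#'   positions considered "inside" (relevant to the form); when given, only
#'   substitution units whose reference tokens all lie inside are kept.
#' @param number_lexicon Character vector of number words.
#' @param abbreviations Data frame with columns `short`, `long`.
#' @return A data frame of class `substitution_records`.
#' @export
classify_substitutions <- function(alignment, inside_positions = NULL,
                                   number_lexicon = .default_number_lexicon,
                                   abbreviations = .default_abbreviations) {
  ops <- alignment$ops
  ref_pos <- cumsum(ops$kind %in% c("correct", "substitution", "deletion"))
  is_sub <- ops$kind == "substitution"
  runs <- rle(is_sub)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  units <- Map(function(s, e) s:e, starts[runs$values], ends[runs$values])
  recs <- lapply(units, function(idx) {
    rseq <- ops$ref_token[idx]; hseq <- ops$hyp_token[idx]
    if (!is.null(inside_positions) && !all(ref_pos[idx] %in% inside_positions))
      return(NULL)
    pm <- phonetic_similarity(rseq, hseq)
    rstr <- paste(rseq, collapse = " "); hstr <- paste(hseq, collapse = " ")
    surface_dist <- as.integer(utils::adist(rstr, hstr))
    is_num <- function(x) any(grepl("^[0-9]+$", x) | tolower(x) %in% number_lexicon)
    abbr <- any(tolower(rstr) %in% abbreviations$short & tolower(hstr) %in% abbreviations$long) ||
            any(tolower(hstr) %in% abbreviations$short & tolower(rstr) %in% abbreviations$long) ||
            any(tolower(rseq) %in% abbreviations$short) || any(tolower(hseq) %in% abbreviations$short)
    data.frame(
      ref = rstr, hyp = hstr, n_words = length(rseq), ps = pm$ps,
      homophone = pm$ps == 100,
      high_similarity = pm$ps > 75,
      short_word = all(nchar(rseq) < 4L),
      spelling_variant_candidate = surface_dist == 1L && pm$ps == 100,
      number_form = is_num(rseq) || is_num(hseq),
      abbreviation_expansion = abbr,
      stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1L))])
  if (is.null(recs))
    recs <- data.frame(ref = character(0), hyp = character(0),
                       n_words = integer(0), ps = numeric(0),
                       homophone = logical(0), high_similarity = logical(0),
                       short_word = logical(0),
                       spelling_variant_candidate = logical(0),
                       number_form = logical(0),
                       abbreviation_expansion = logical(0),
                       stringsAsFactors = FALSE)
  recs$correction_candidate <- recs$homophone | recs$high_similarity
  class(recs) <- c("substitution_records", "data.frame")
  recs
}

#' Summarize a corpus error profile
#'
#' Aggregates substitution records and alignment ops into an error profile:
#' the number of unique errors (set semantics over lowercased
#' reference/hypothesis pairs, after multi-word merging), error-class
#' proportions over substitution records, and the top-k most frequent
#' substitution, insertion and deletion patterns.
#'
#' @param records A `substitution_records` data frame (rows from one or many
#'   documents row-bound together).
#' @param alignments Optional list of `alignment_result` objects used to
#'   tally insertion and deletion patterns.
#' @param k Number of top patterns to report.
#' @return An `error_profile` list.
#' @export
error_profile <- function(records, alignments = NULL, k = 10L) {
  key <- paste(tolower(records$ref), "=>", tolower(records$hyp))
  sub_tab <- sort(table(key), decreasing = TRUE)
  ins <- del <- character(0L)
  if (!is.null(alignments)) {
    if (inherits(alignments, "alignment_result")) alignments <- list(alignments)
    for (a in alignments) {
      ins <- c(ins, a$ops$hyp_token[a$ops$kind == "insertion"])
      del <- c(del, a$ops$ref_token[a$ops$kind == "deletion"])
    }
  }
  ins_tab <- sort(table(tolower(ins)), decreasing = TRUE)
  del_tab <- sort(table(tolower(del)), decreasing = TRUE)
  uniq_ins <- length(unique(tolower(ins)))
  uniq_del <- length(unique(tolower(del)))
  n <- nrow(records)
  prop <- function(flag) if (n > 0L) mean(records[[flag]]) else NA_real_
  structure(list(
    n_substitution_records = n,
    unique_substitutions = length(sub_tab),
    unique_errors = length(sub_tab) + uniq_ins + uniq_del,
    class_proportions = c(
      homophone = prop("homophone"),
      high_similarity = prop("high_similarity"),
      short_word = prop("short_word"),
      spelling_variant_candidate = prop("spelling_variant_candidate"),
      number_form = prop("number_form"),
      abbreviation_expansion = prop("abbreviation_expansion"),
      correction_candidate = prop("correction_candidate")),
    top_substitutions = utils::head(sub_tab, k),
    top_insertions = utils::head(ins_tab, k),
    top_deletions = utils::head(del_tab, k)),
    class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("<error_profile> %d substitution records, %d unique errors\n",
              x$n_substitution_records, x$unique_errors))
  cat("  class proportions:\n")
  print(round(x$class_proportions, 3))
  invisible(x)
}
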