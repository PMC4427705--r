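#' Double Metaphone phonetic encoding
#'
#' Encodes a word into a consonant-skeleton code in which similar sounds share
#' the same symbol (for example "b" and "p" both map to "P"), following the
#' Double Metaphone algorithm: a primary code and, where pronunciation is
#' ambiguous (Slavic, Germanic, French, Spanish accent variants), an alternate
#' code. Codes are truncated to `max_code_len` symbols (4 by default, the
#' conventional setting). The theta sound of "th" is written as the digit `0`.
#'
#' @param word A single non-empty word (letters; case-insensitive).
#' @param max_code_len Maximum code length, default 4.
#' @return An object of class `phonetic_encoding`: list with `word`,
#'   `primary_code` and `alternate_code`.
#' @examples
#' encode_word("four")$primary_code  # equals encode_word("for")$primary_code
#' @export
encode_word <- function(word, max_code_len = 4L) {
  if (!is.character(word) || length(word) != 1L || is.na(word) || !nzchar(word))
    stop("encode_word() requires a single non-empty word")
  codes <- .double_metaphone(word, max_code_len)
  structure(list(word = word, primary_code = codes[[1L]],
                 alternate_code = codes[[2L]]),
            class = "phonetic_encoding")
}

#' Encode a multi-word sequence
#'
#' Double Metaphone encodes one word at a time; multi-word error units are
#' compared by first encoding each word, then concatenating the per-word
#' primary codes in order.
#'
#' @param words Non-empty character vector of words.
#' @param alternate Use alternate codes where defined instead of primary.
#' @param max_code_len Per-word code length limit.
#' @return A single concatenated code string.
#' @export
encode_sequence <- function(words, alternate = FALSE, max_code_len = 4L) {
  if (length(words) < 1L) stop("encode_sequence() requires at least one word")
  codes <- vapply(words, function(w) {
    e <- encode_word(w, max_code_len)
    if (alternate && nzchar(e$alternate_code)) e$alternate_code else e$primary_code
  }, character(1L), USE.NAMES = FALSE)
  paste(codes, collapse = "")
}

#' @export
print.phonetic_encoding <- function(x, ...) {
  cat(sprintf("<phonetic_encoding> %s -> %s%s\n", x$word, x$primary_code,
              if (!identical(x$alternate_code, x$primary_code))
                paste0(" / ", x$alternate_code) else ""))
  invisible(x)
}

# --- algorithm internals (0-based indices, mirroring the published reference) -

.dm_vowels <- c("A", "E", "I", "O", "U", "Y")

.double_metaphone <- function(word, max_code_len = 4L) {
  value <- toupper(trimws(word))
  value <- gsub("[^A-Z]", "", value)
  n <- nchar(value)
  if (n == 0L) return(list("", ""))

  ch_at <- function(i) if (i < 0L || i >= n) "" else substr(value, i + 1L, i + 1L)
  is_vowel <- function(i) ch_at(i) %in% .dm_vowels
  contains <- function(start, len, ...) {
    if (start < 0L || start + len > n) return(FALSE)
    substr(value, start + 1L, start + len) %in% c(...)
  }
  slavo <- grepl("W|K|CZ|WITZ", value)

  prim <- character(0L); alt <- character(0L)
  app  <- function(p, a = p) { if (nzchar(p)) prim <<- c(prim, p)
                               if (nzchar(a)) alt  <<- c(alt, a) }
  app_p <- function(p) prim <<- c(prim, p)
  app_a <- function(a) alt  <<- c(alt, a)

  index <- 0L
  if (contains(0L, 2L, "GN", "KN", "PN", "WR", "PS")) index <- 1L
  if (ch_at(0L) == "X") { app("S"); index <- 1L }

  while ((length(prim) < max_code_len || length(alt) < max_code_len) &&
         index < n) {
    ch <- ch_at(index)
    nxt <- ch_at(index + 1L)
    last <- n - 1L

    if (ch %in% .dm_vowels) {
      if (index == 0L) app("A")
      index <- index + 1L

    } else if (ch == "B") {
      app("P"); index <- index + (if (nxt == "B") 2L else 1L)

    } else if (ch == "C") {
      if (index > 1L && !is_vowel(index - 2L) && contains(index - 1L, 3L, "ACH") &&
          ch_at(index + 2L) != "I" &&
          (ch_at(index + 2L) != "E" || contains(index - 2L, 6L, "BACHER", "MACHER"))) {
        app("K"); index <- index + 2L
      } else if (index == 0L && contains(index, 6L, "CAESAR")) {
        app("S"); index <- index + 2L
      } else if (contains(index, 4L, "CHIA")) {
        app("K"); index <- index + 2L
      } else if (contains(index, 2L, "CH")) {
        if (index > 0L && contains(index, 4L, "CHAE")) {
          app("K", "X"); index <- index + 2L
        } else if (index == 0L &&
                   (contains(index + 1L, 5L, "HARAC", "HARIS") ||
                    contains(index + 1L, 3L, "HOR", "HYM", "HIA", "HEM")) &&
                   !contains(0L, 5L, "CHORE")) {
          app("K"); index <- index + 2L
        } else if (contains(0L, 4L, "VAN ", "VON ") || contains(0L, 3L, "SCH") ||
                   contains(index - 2L, 6L, "ORCHES", "ARCHIT", "ORCHID") ||
                   contains(index + 2L, 1L, "T", "S") ||
                   ((contains(index - 1L, 1L, "A", "O", "U", "E") || index == 0L) &&
                    (contains(index + 2L, 1L, "L", "R", "N", "M", "B", "H", "F", "V", "W", " ") ||
                     index + 1L == last))) {
          app("K"); index <- index + 2L
        } else {
          if (index > 0L) {
            if (contains(0L, 2L, "MC")) app("K") else app("X", "K")
          } else app("X")
          index <- index + 2L
        }
      } else if (contains(index, 2L, "CZ") && !contains(index - 2L, 4L, "WICZ")) {
        app("S", "X"); index <- index + 2L
      } else if (contains(index + 1L, 3L, "CIA")) {
        app("X"); index <- index + 3L
      } else if (contains(index, 2L, "CC") && !(index == 1L && ch_at(0L) == "M")) {
        if (contains(index + 2L, 1L, "I", "E", "H") && !contains(index + 2L, 2L, "HU")) {
          if ((index == 1L && ch_at(index - 1L) == "A") ||
              contains(index - 1L, 5L, "UCCEE", "UCCES")) app("KS") else app("X")
          index <- index + 3L
        } else { app("K"); index <- index + 2L }
      } else if (contains(index, 2L, "CK", "CG", "CQ")) {
        app("K"); index <- index + 2L
      } else if (contains(index, 2L, "CI", "CE", "CY")) {
        if (contains(index, 3L, "CIO", "CIE", "CIA")) app("S", "X") else app("S")
        index <- index + 2L
      } else {
        app("K")
        index <- index + (if (contains(index + 1L, 2L, " C", " Q", " G")) 3L
                          else if (contains(index + 1L, 1L, "C", "K", "Q") &&
                                   !contains(index + 1L, 2L, "CE", "CI")) 2L else 1L)
      }

    } else if (ch == "D") {
      if (contains(index, 2L, "DG")) {
        if (contains(index + 2L, 1L, "I", "E", "Y")) { app("J"); index <- index + 3L }
        else { app("TK"); index <- index + 2L }
      } else if (contains(index, 2L, "DT", "DD")) {
        app("T"); index <- index + 2L
      } else { app("T"); index <- index + 1L }

    } else if (ch == "F") {
      app("F"); index <- index + (if (nxt == "F") 2L else 1L)

    } else if (ch == "G") {
      if (nxt == "H") {
        if (index > 0L && !is_vowel(index - 1L)) {
          app("K"); index <- index + 2L
        } else if (index == 0L) {
          if (ch_at(index + 2L) == "I") app("J") else app("K")
          index <- index + 2L
        } else if ((index > 1L && contains(index - 2L, 1L, "B", "H", "D")) ||
                   (index > 2L && contains(index - 3L, 1L, "B", "H", "D")) ||
                   (index > 3L && contains(index - 4L, 1L, "B", "H"))) {
          index <- index + 2L
        } else {
          if (index > 2L && ch_at(index - 1L) == "U" &&
              contains(index - 3L, 1L, "C", "G", "L", "R", "T")) app("F")
          else if (index > 0L && ch_at(index - 1L) != "I") app("K")
          index <- index + 2L
        }
      } else if (nxt == "N") {
        if (index == 1L && is_vowel(0L) && !slavo) { app_p("KN"); app_a("N") }
        else if (!contains(index + 2L, 2L, "EY") && ch_at(index + 1L) != "Y" && !slavo) {
          app_p("N"); app_a("KN")
        } else app("KN")
        index <- index + 2L
      } else if (contains(index + 1L, 2L, "LI") && !slavo) {
        app_p("KL"); app_a("L"); index <- index + 2L
      } else if (index == 0L &&
                 (ch_at(index + 1L) == "Y" ||
                  contains(index + 1L, 2L, "ES", "EP", "EB", "EL", "EY", "IB",
                           "IL", "IN", "IE", "EI", "ER"))) {
        app("K", "J"); index <- index + 2L
      } else if ((contains(index + 1L, 2L, "ER") || ch_at(index + 1L) == "Y") &&
                 !contains(0L, 6L, "DANGER", "RANGER", "MANGER") &&
                 !contains(index - 1L, 1L, "E", "I") &&
                 !contains(index - 1L, 3L, "RGY", "OGY")) {
        app("K", "J"); index <- index + 2L
      } else if (contains(index + 1L, 1L, "E", "I", "Y") ||
                 contains(index - 1L, 4L, "AGGI", "OGGI")) {
        if (contains(0L, 4L, "VAN ", "VON ") || contains(0L, 3L, "SCH") ||
            contains(index + 1L, 2L, "ET")) app("K")
        else if (contains(index + 1L, 3L, "IER")) app("J")
        else app("J", "K")
        index <- index + 2L
      } else {
        app("K"); index <- index + (if (nxt == "G") 2L else 1L)
      }

    } else if (ch == "H") {
      if ((index == 0L || is_vowel(index - 1L)) && is_vowel(index + 1L)) {
        app("H"); index <- index + 2L
      } else index <- index + 1L

    } else if (ch == "J") {
      if (contains(index, 4L, "JOSE") || contains(0L, 4L, "SAN ")) {
        if ((index == 0L && (ch_at(index + 4L) == " " || n == index + 4L)) ||
            contains(0L, 4L, "SAN "))
          app("H") else app("J", "H")
        index <- index + 1L
      } else {
        if (index == 0L) app("J", "A")
        else if (is_vowel(index - 1L) && !slavo && (nxt == "A" || nxt == "O"))
          app("J", "H")
        else if (index == last) app_p("J")
        else if (!contains(index + 1L, 1L, "L", "T", "K", "S", "N", "M", "B", "Z") &&
                 !contains(index - 1L, 1L, "S", "K", "L")) app("J")
        index <- index + (if (nxt == "J") 2L else 1L)
      }

    } else if (ch == "K") {
      app("K"); index <- index + (if (nxt == "K") 2L else 1L)

    } else if (ch == "L") {
      if (nxt == "L") {
        cond <- (index == n - 3L && contains(index - 1L, 4L, "ILLO", "ILLA", "ALLE")) ||
          ((contains(last - 1L, 2L, "AS", "OS") || contains(last, 1L, "A", "O")) &&
           contains(index - 1L, 4L, "ALLE"))
        if (cond) app_p("L") else app("L")
        index <- index + 2L
      } else { app("L"); index <- index + 1L }

    } else if (ch == "M") {
      app("M")
      dbl <- (contains(index - 1L, 3L, "UMB") &&
                (index + 1L == last || contains(index + 2L, 2L, "ER"))) || nxt == "M"
      index <- index + (if (dbl) 2L else 1L)

    } else if (ch == "N") {
      app("N"); index <- index + (if (nxt == "N") 2L else 1L)

    } else if (ch == "P") {
      if (nxt == "H") { app("F"); index <- index + 2L }
      else { app("P"); index <- index + (if (contains(index + 1L, 1L, "P", "B")) 2L else 1L) }

    } else if (ch == "Q") {
      app("K"); index <- index + (if (nxt == "Q") 2L else 1L)

    } else if (ch == "R") {
      if (index == last && !slavo && contains(index - 2L, 2L, "IE") &&
          !contains(index - 4L, 2L, "ME", "MA")) app_a("R") else app("R")
      index <- index + (if (nxt == "R") 2L else 1L)

    } else if (ch == "S") {
      if (contains(index - 1L, 3L, "ISL", "YSL")) {
        index <- index + 1L
      } else if (index == 0L && contains(index, 5L, "SUGAR")) {
        app("X", "S"); index <- index + 1L
      } else if (contains(index, 2L, "SH")) {
        if (contains(index + 1L, 4L, "HEIM", "HOEK", "HOLM", "HOLZ")) app("S") else app("X")
        index <- index + 2L
      } else if (contains(index, 3L, "SIO", "SIA") || contains(index, 4L, "SIAN")) {
        if (!slavo) app("S", "X") else app("S")
        index <- index + 3L
      } else if ((index == 0L && contains(index + 1L, 1L, "M", "N", "L", "W")) ||
                 contains(index + 1L, 1L, "Z")) {
        app("S", "X")
        index <- index + (if (contains(index + 1L, 1L, "Z")) 2L else 1L)
      } else if (contains(index, 2L, "SC")) {
        if (ch_at(index + 2L) == "H") {
          if (contains(index + 3L, 2L, "OO", "ER", "EN", "UY", "ED", "EM")) {
            if (contains(index + 3L, 2L, "ER", "EN")) app("X", "SK") else app("SK")
          } else {
            if (index == 0L && !is_vowel(3L) && ch_at(3L) != "W") app("X", "S") else app("X")
          }
          index <- index + 3L
        } else if (contains(index + 2L, 1L, "I", "E", "Y")) {
          app("S"); index <- index + 3L
        } else { app("SK"); index <- index + 3L }
      } else {
        if (index == last && contains(index - 2L, 2L, "AI", "OI")) app_a("S") else app("S")
        index <- index + (if (contains(index + 1L, 1L, "S", "Z")) 2L else 1L)
      }

    } else if (ch == "T") {
      if (contains(index, 4L, "TION")) {
        app("X"); index <- index + 3L
      } else if (contains(index, 3L, "TIA", "TCH")) {
        app("X"); index <- index + 3L
      } else if (contains(index, 2L, "TH") || contains(index, 3L, "TTH")) {
        if (contains(index + 2L, 2L, "OM", "AM") || contains(0L, 4L, "VAN ", "VON ") ||
            contains(0L, 3L, "SCH")) app("T") else app("0", "T")
        index <- index + 2L
      } else {
        app("T"); index <- index + (if (contains(index + 1L, 1L, "T", "D")) 2L else 1L)
      }

    } else if (ch == "V") {
      app("F"); index <- index + (if (nxt == "V") 2L else 1L)

    } else if (ch == "W") {
      if (contains(index, 2L, "WR")) {
        app("R"); index <- index + 2L
      } else if (index == 0L && (is_vowel(index + 1L) || contains(index, 2L, "WH"))) {
        if (is_vowel(index + 1L)) app("A", "F") else app("A")
        index <- index + 1L
      } else if ((index == last && is_vowel(index - 1L)) ||
                 contains(index - 1L, 5L, "EWSKI", "EWSKY", "OWSKI", "OWSKY") ||
                 contains(0L, 3L, "SCH")) {
        app_a("F"); index <- index + 1L
      } else if (contains(index, 4L, "WICZ", "WITZ")) {
        app("TS", "FX"); index <- index + 4L
      } else index <- index + 1L

    } else if (ch == "X") {
      if (!(index == last && (contains(index - 3L, 3L, "IAU", "EAU") ||
                              contains(index - 2L, 2L, "AU", "OU")))) app("KS")
      index <- index + (if (contains(index + 1L, 1L, "C", "X")) 2L else 1L)

    } else if (ch == "Z") {
      if (nxt == "H") { app("J"); index <- index + 2L }
      else {
        if (contains(index + 1L, 2L, "ZO", "ZI", "ZA") ||
            (slavo && index > 0L && ch_at(index - 1L) != "T")) app("S", "TS") else app("S")
        index <- index + (if (nxt == "Z") 2L else 1L)
      }

    } else index <- index + 1L
  }

  trunc4 <- function(x) {
    s <- paste(x, collapse = "")
    if (nchar(s) > max_code_len) substr(s, 1L, max_code_len) else s
  }
  list(trunc4(prim), trunc4(alt))
}
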