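#' Token-by-feature matrices in the CRF++ column convention
#'
#' A feature matrix holds one row per token: the token surface first, then
#' feature columns, and — when annotated — the category label as the last
#' column. All rows of a document have the same column count; absent values
#' carry the placeholder `"_"`. Files use tab-separated columns with a blank
#' line between documents.
#'
#' @param doc_id Document identifier.
#' @param cells Character matrix, tokens in rows.
#' @param annotated Whether the last column is the label column.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(doc_id, cells, annotated = TRUE) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  cells[is.na(cells) | cells == ""] <- "_"
  structure(list(doc_id = as.character(doc_id), cells = cells,
                 annotated = isTRUE(annotated)),
            class = "feature_matrix")
}

#' @rdname feature_matrix
#' @param fm A `feature_matrix`.
#' @export
fm_tokens <- function(fm) unname(fm$cells[, 1L])

#' @rdname feature_matrix
#' @export
fm_labels <- function(fm) {
  if (!fm$annotated) stop("feature matrix is not annotated")
  as.integer(fm$cells[, ncol(fm$cells)])
}

#' @rdname feature_matrix
#' @export
fm_n_feature_cols <- function(fm) ncol(fm$cells) - if (fm$annotated) 1L else 0L

#' Read a CRF++ column file
#'
#' One token per line, whitespace-separated columns, blank line between
#' documents. Ragged rows raise a parse error naming the offending line.
#'
#' @param path File path.
#' @param annotated Whether the last column holds labels.
#' @return A list of `feature_matrix` objects (empty list for an empty file).
#' @export
read_crfpp <- function(path, annotated = TRUE) {
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  doc_id <- cumsum(c(TRUE, blank[-length(blank)])) * NA
  grp <- cumsum(blank) + 1L
  out <- list(); counter <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g & !blank)
    if (length(idx) == 0L) next
    rows <- strsplit(trimws(lines[idx]), "[ \t]+")
    ncols <- lengths(rows)
    if (length(unique(ncols)) != 1L) {
      bad <- idx[which(ncols != ncols[1L])[1L]]
      stop("ragged CRF++ row at line ", bad, " of ", path,
           " (expected ", ncols[1L], " columns, got ",
           ncols[which(ncols != ncols[1L])[1L]], ")")
    }
    counter <- counter + 1L
    out[[counter]] <- feature_matrix(sprintf("doc%03d", counter),
                                     do.call(rbind, rows), annotated)
  }
  out
}

#' Write CRF++ column files
#'
#' Tab-separated rows, one blank line after every document (fixed trailing
#' newline policy so that `write_crfpp()` then [read_crfpp()] round-trips).
#'
#' @param matrices A `feature_matrix` or list of them.
#' @param path Output file path.
#' @export
write_crfpp <- function(matrices, path) {
  if (inherits(matrices, "feature_matrix")) matrices <- list(matrices)
  chunks <- lapply(matrices, function(fm)
    c(apply(fm$cells, 1L, paste, collapse = "\t"), ""))
  writeLines(unlist(chunks), path)
  invisible(path)
}

#' Join multi-valued feature cells
#'
#' CRF++ columns are whitespace-delimited, so multi-valued outputs (concept
#' candidates, dependents) are serialized into one cell with a fixed `|`
#' separator; whitespace and literal `|` inside values are replaced by `_`.
#'
#' @param values Character vector of values (possibly empty).
#' @return A single cell string (`"_"` when no values).
#' @export
join_values <- function(values) {
  values <- values[!is.na(values) & nzchar(values)]
  if (length(values) == 0L) return("_")
  paste(gsub("[|[:space:]]+", "_", values), collapse = "|")
}

# ---- feature template -------------------------------------------------------

#' CRF feature templates
#'
#' A template is a set of unigram macros and bigram macros; each macro
#' conjoins feature cells at `(row offset, column)` positions relative to the
#' current token (offsets -1, 0, +1). The reference template implements seven
#' groups: in the unigram part, every feature of the current location alone,
#' of the previous location alone, and of the next location alone; the
#' pairwise previous/current and current/next correlations over every
#' feature; and the conjunction of all features of the current location. In
#' the bigram part, the features of the current location are combined with
#' the predicted category of the previous location.
#'
#' @param n_feature_cols Number of feature columns (token surface included).
#' @return A `crf_template`.
#' @export
default_template <- function(n_feature_cols) {
  stopifnot(n_feature_cols >= 1L)
  cols <- seq_len(n_feature_cols) - 1L
  uni <- list(); bi <- list()
  mk <- function(off, col) cbind(offset = off, col = col)
  for (c in cols) uni[[sprintf("Ua%02d", c)]] <- mk(0L, c)
  for (c in cols) uni[[sprintf("Ub%02d", c)]] <- mk(-1L, c)
  for (c in cols) uni[[sprintf("Uc%02d", c)]] <- mk(1L, c)
  for (c in cols) uni[[sprintf("Ud%02d", c)]] <- mk(c(-1L, 0L), c(c, c))
  for (c in cols) uni[[sprintf("Ue%02d", c)]] <- mk(c(0L, 1L), c(c, c))
  uni[["Uf00"]] <- mk(rep(0L, length(cols)), cols)
  for (c in cols) bi[[sprintf("B%02d", c)]] <- mk(0L, c)
  structure(list(unigrams = uni, bigrams = bi), class = "crf_template")
}

#' Parse a CRF++ template file
#'
#' Supports the CRF++ macro syntax: lines like `U00:%x[0,0]` or
#' `U12:%x[-1,1]/%x[0,1]`, `B`-prefixed bigram macros, a bare `B` (pure
#' label-transition macro with no feature cells), and `#` comments.
#'
#' @param path Template file path.
#' @return A `crf_template`.
#' @export
read_template <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  uni <- list(); bi <- list()
  for (ln in lines) {
    name <- sub(":.*$", "", ln)
    body <- if (grepl(":", ln, fixed = TRUE)) sub("^[^:]*:", "", ln) else ""
    m <- gregexpr("%x\\[(-?[0-9]+),([0-9]+)\\]", body, perl = TRUE)[[1L]]
    tuples <- NULL
    if (m[1L] != -1L) {
      parts <- regmatches(body, gregexpr("%x\\[(-?[0-9]+),([0-9]+)\\]", body))[[1L]]
      off <- as.integer(sub("%x\\[(-?[0-9]+),.*", "\\1", parts))
      col <- as.integer(sub(".*,([0-9]+)\\]", "\\1", parts))
      if (any(off < -1L | off > 1L))
        stop("template error: offsets must be in {-1, 0, +1}")
      tuples <- cbind(offset = off, col = col)
    } else tuples <- cbind(offset = integer(0), col = integer(0))
    if (startsWith(name, "U")) uni[[name]] <- tuples
    else if (startsWith(name, "B")) bi[[name]] <- tuples
    else stop("template error: macro must start with U or B: ", ln)
  }
  structure(list(unigrams = uni, bigrams = bi), class = "crf_template")
}

#' Write a template in CRF++ macro syntax
#' @param template A `crf_template`.
#' @param path Output path.
#' @export
write_template <- function(template, path) {
  fmt <- function(name, tuples) {
    if (nrow(tuples) == 0L) return(name)
    paste0(name, ":", paste(sprintf("%%x[%d,%d]", tuples[, "offset"],
                                    tuples[, "col"]), collapse = "/"))
  }
  lines <- c(mapply(fmt, names(template$unigrams), template$unigrams),
             mapply(fmt, names(template$bigrams), template$bigrams))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Check that a template encodes the seven reference groups
#'
#' @param template A `crf_template`.
#' @param n_feature_cols Number of feature columns it should cover.
#' @return `TRUE`, or `FALSE` with attribute `missing` naming absent groups.
#' @export
verify_template <- function(template, n_feature_cols) {
  ref <- default_template(n_feature_cols)
  canon <- function(macros) {
    keys <- vapply(macros, function(m)
      paste(sprintf("%d,%d", m[, "offset"], m[, "col"]), collapse = ";"),
      character(1L))
    sort(unname(keys))
  }
  missing <- character(0L)
  ref_uni <- canon(ref$unigrams); got_uni <- canon(template$unigrams)
  if (!all(ref_uni %in% got_uni)) missing <- c(missing, "unigram groups incomplete")
  ref_bi <- canon(ref$bigrams); got_bi <- canon(template$bigrams)
  if (!all(ref_bi %in% got_bi)) missing <- c(missing, "bigram group incomplete")
  ok <- length(missing) == 0L
  if (!ok) attr(ok, "missing") <- missing
  ok
}

#' Expand a template at one token position
#'
#' Produces the deterministic unigram and bigram feature strings for position
#' `t` of a document. Offsets that fall outside the document use the boundary
#' sentinels `_B-1` (before the first token) and `_B+1` (after the last).
#'
#' @param template A `crf_template`.
#' @param matrix A `feature_matrix`.
#' @param t 1-based token position.
#' @return List with character vectors `uni` and `bi`.
#' @export
expand_template <- function(template, matrix, t) {
  n <- nrow(matrix$cells)
  ncol_feat <- fm_n_feature_cols(matrix)
  if (t < 1L || t > n) stop("position out of range")
  cell <- function(off, col) {
    if (col + 1L > ncol_feat)
      stop("template error: column index ", col, " out of range (",
           ncol_feat, " feature columns)")
    i <- t + off
    if (i < 1L) "_B-1" else if (i > n) "_B+1" else matrix$cells[i, col + 1L]
  }
  expand <- function(macros) vapply(names(macros), function(nm) {
    m <- macros[[nm]]
    if (nrow(m) == 0L) return(nm)
    vals <- mapply(cell, m[, "offset"], m[, "col"])
    paste0(nm, ":", paste(vals, collapse = "/"))
  }, character(1L), USE.NAMES = FALSE)
  list(uni = expand(template$unigrams), bi = expand(template$bigrams))
}
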