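#' @title The structured handover form schema
#'
#' @description The handover form consists of six headings — HANDOVER NURSE,
#' PATIENT INTRODUCTION, MY SHIFT, APPOINTMENTS, MEDICATION and FUTURE CARE —
#' holding respectively 5, 18, 8, 12, 3 and 3 mutually exclusive categories,
#' plus a single NA category for text relevant to no form slot: 50 categories
#' in total. Every token of a handover document is assigned exactly one
#' category id. A schema object is a data frame with columns `id`, `heading`,
#' `subheading`, `subsubheading` and a derived display `name`, carrying class
#' `handover_schema` and a `level` attribute (`"fine"` or `"heading"`).
#'
#' @name handover_schema
NULL

.heading_order <- c("HANDOVER NURSE", "PATIENT INTRODUCTION", "MY SHIFT",
                    "APPOINTMENTS", "MEDICATION", "FUTURE CARE", "NA")
.heading_counts <- c("HANDOVER NURSE" = 5L, "PATIENT INTRODUCTION" = 18L,
                     "MY SHIFT" = 8L, "APPOINTMENTS" = 12L,
                     "MEDICATION" = 3L, "FUTURE CARE" = 3L, "NA" = 1L)

.make_schema <- function(df, level = "fine") {
  df$id <- as.integer(df$id)
  for (col in c("heading", "subheading", "subsubheading"))
    if (is.null(df[[col]])) df[[col]] <- ""
  df$subheading[is.na(df$subheading)] <- ""
  df$subsubheading[is.na(df$subsubheading)] <- ""
  nm <- ifelse(df$heading == "NA", "NA",
               paste0(df$heading,
                      ifelse(df$subheading == "", "", paste0(": ", df$subheading)),
                      ifelse(df$subsubheading == "", "", paste0(": ", df$subsubheading))))
  df$name <- nm
  df <- df[, c("id", "heading", "subheading", "subsubheading", "name")]
  rownames(df) <- NULL
  class(df) <- c("handover_schema", "data.frame")
  attr(df, "level") <- level
  df
}

.validate_schema <- function(schema) {
  if (anyDuplicated(schema$id))
    stop("schema error: duplicate category id(s): ",
         paste(unique(schema$id[duplicated(schema$id)]), collapse = ", "))
  if (anyDuplicated(schema$name))
    stop("schema error: category names are not mutually exclusive")
  if (sum(schema$heading == "NA") != 1L)
    stop("schema error: exactly one category must carry the NA heading")
  if (identical(attr(schema, "level"), "fine")) {
    if (nrow(schema) != 50L)
      stop("schema error: expected 50 categories, got ", nrow(schema))
    got <- table(factor(schema$heading, levels = .heading_order))
    bad <- .heading_counts[names(got)] != as.integer(got)
    if (any(bad))
      stop("schema error: wrong per-heading category count for ",
           paste(names(got)[bad], collapse = ", "),
           " (expected 5/18/8/12/3/3 plus one NA)")
  }
  invisible(schema)
}

#' Load a handover form schema
#'
#' Reads a schema definition file: tab-separated with a header line
#' `id  heading  subheading  subsubheading` and one category per line;
#' lines starting with `#` are comments. The default file shipped with the
#' package encodes the 50-category form (6 headings plus NA). Names attested
#' in the study prose are verbatim; the remainder of the default file is a
#' synthetic reconstruction and can be replaced by any conforming file.
#'
#' @param path Path to a schema file. Defaults to the packaged schema.
#' @return A `handover_schema` data frame of 50 categories.
#' @examples
#' sch <- load_schema()
#' nrow(sch)                       # 50
#' table(sch$heading)["PATIENT INTRODUCTION"]  # 18
#' @export
load_schema <- function(path = system.file("extdata", "handover_form_schema.tsv",
                                           package = "handoverNLP")) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("id", "heading", "subheading", "subsubheading")
  if (!all(need %in% names(df)))
    stop("schema error: file must have columns ", paste(need, collapse = ", "))
  sch <- .make_schema(df)
  .validate_schema(sch)
  sch
}

#' Write a schema definition file
#'
#' Writes the canonical tab-separated schema representation read by
#' [load_schema()]; `write_schema()` then [load_schema()] round-trips to an
#' identical object, and a second write is byte-identical.
#'
#' @param schema A `handover_schema`.
#' @param path Output path.
#' @export
write_schema <- function(schema, path) {
  lines <- c(paste("id", "heading", "subheading", "subsubheading", sep = "\t"),
             paste(schema$id, schema$heading, schema$subheading,
                   schema$subsubheading, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' The NA (irrelevant text) category id of a schema
#' @param schema A `handover_schema`.
#' @return Integer id of the NA category.
#' @export
na_id <- function(schema) schema$id[schema$heading == "NA"]

#' Heading-level view of a schema
#'
#' Collapses the fine-grained 50-category schema to its 7 heading-level
#' values (six headings plus NA), in heading order with ids 1..7.
#'
#' @param schema A fine-grained `handover_schema`.
#' @return A `handover_schema` with `level = "heading"`.
#' @export
heading_schema <- function(schema) {
  if (identical(attr(schema, "level"), "heading")) return(schema)
  df <- data.frame(id = seq_along(.heading_order), heading = .heading_order,
                   subheading = "", subsubheading = "",
                   stringsAsFactors = FALSE)
  .make_schema(df, level = "heading")
}

#' Map fine-grained category ids to heading-level ids
#' @param ids Integer vector of fine category ids.
#' @param schema The fine-grained schema the ids belong to.
#' @return Integer vector of heading-level ids (1..7).
#' @export
heading_of <- function(ids, schema) {
  pos <- match(ids, schema$id)
  if (anyNA(pos)) stop("unknown category id(s): ",
                       paste(unique(ids[is.na(pos)]), collapse = ", "))
  match(schema$heading[pos], .heading_order)
}

#' Construct a token-annotated handover document
#'
#' A document is an ordered token sequence with exactly one category label per
#' token; text relevant to no form slot carries the NA category id.
#'
#' @param doc_id Document identifier string.
#' @param tokens Character vector of surface tokens.
#' @param labels Integer vector of category ids, one per token.
#' @param schema Schema the labels refer to.
#' @return An `annotated_document` (list with `doc_id`, `tokens`, `labels`).
#' @export
annotated_document <- function(doc_id, tokens, labels, schema) {
  labels <- as.integer(labels)
  if (length(tokens) != length(labels))
    stop("annotated document invariant violated: ", length(tokens),
         " tokens but ", length(labels), " labels")
  if (!all(labels %in% schema$id))
    stop("unknown category id(s): ",
         paste(unique(labels[!labels %in% schema$id]), collapse = ", "))
  structure(list(doc_id = as.character(doc_id), tokens = as.character(tokens),
                 labels = labels),
            class = "annotated_document",
            level = attr(schema, "level"))
}

#' Abstract fine-grained labels to heading level
#'
#' Replaces every fine-grained label of a document by its heading-level
#' category (ids of [heading_schema()]); NA stays NA and the token sequence is
#' unchanged. The operation is idempotent: a heading-level document is
#' returned as is.
#'
#' @param doc An `annotated_document`.
#' @param schema The fine-grained schema the document was annotated against.
#' @return An `annotated_document` at heading level.
#' @export
abstract_labels <- function(doc, schema) {
  if (identical(attr(doc, "level"), "heading")) return(doc)
  annotated_document(doc$doc_id, doc$tokens, heading_of(doc$labels, schema),
                     heading_schema(schema))
}

#' @export
print.handover_schema <- function(x, ...) {
  cat("<handover_schema> ", nrow(x), " categories (level: ",
      attr(x, "level"), ")\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
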