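# The document container used throughout the package.
#
# A `seqc_document` is a plain list: tokenized title, abstract sentences,
# optional body sections (each a titled list of sentences), keywords, date,
# optional gold species labels and a `masked` flag.

#' Construct a document
#'
#' @param doc_id non-empty identifier (PMID, PMC id, or synthetic id).
#' @param title character vector of title tokens (may be empty).
#' @param abstract list of sentences, each a non-empty character vector of
#'   tokens.
#' @param sections list of `list(title =, sentences =)` entries in document
#'   order; `sentences` like `abstract`. May be empty (abstract-only).
#' @param keywords character vector.
#' @param date ISO date string or "".
#' @param labels character vector of canonical species labels, or `NULL`
#'   when unlabeled.
#' @param masked logical; `TRUE` after species mentions were replaced by
#'   [SPECIES_MASK].
#' @return object of class `seqc_document`.
#' @export
seqc_document <- function(doc_id, title = character(), abstract = list(),
                          sections = list(), keywords = character(),
                          date = "", labels = NULL, masked = FALSE) {
  if (!is_string(doc_id) || !nzchar(doc_id))
    seqc_abort("parse", "document id must be a non-empty string")
  abstract <- lapply(abstract, as.character)
  if (any(vapply(abstract, length, 1L) == 0L))
    seqc_abort("parse", "document '%s' has an empty abstract sentence", doc_id)
  sections <- lapply(sections, function(s) {
    sent <- lapply(s$sentences %||% list(), as.character)
    if (any(vapply(sent, length, 1L) == 0L))
      seqc_abort("parse", "document '%s' has an empty body sentence", doc_id)
    list(title = as.character(s$title %||% ""), sentences = sent)
  })
  structure(list(
    doc_id = doc_id,
    title = as.character(title),
    abstract = abstract,
    sections = sections,
    keywords = as.character(keywords),
    date = as.character(date),
    labels = if (is.null(labels)) NULL else sort(unique(as.character(labels))),
    masked = isTRUE(masked)
  ), class = "seqc_document")
}

#' @export
print.seqc_document <- function(x, ...) {
  nb <- sum(vapply(x$sections, function(s) length(s$sentences), 1L))
  cat(sprintf(
    "<seqc_document %s: %d title tokens, %d abstract sentences, %d sections (%d sentences)%s%s>\n",
    x$doc_id, length(x$title), length(x$abstract), length(x$sections), nb,
    if (x$masked) ", masked" else "",
    if (is.null(x$labels)) "" else sprintf(", labels={%s}", paste(x$labels, collapse = ","))
  ))
  invisible(x)
}

#' All sentences of a document
#'
#' Title (as a pseudo-sentence, when non-empty), abstract sentences, then
#' body sentences in section order.
#'
#' @param doc a `seqc_document`.
#' @return list of token vectors.
#' @export
doc_sentences <- function(doc) {
  body <- unlist(lapply(doc$sections, `[[`, "sentences"), recursive = FALSE)
  out <- c(
    if (length(doc$title) > 0L) list(doc$title) else list(),
    doc$abstract,
    body %||% list()
  )
  out
}

#' Flat token stream of a document
#' @param doc a `seqc_document`.
#' @return character vector.
#' @export
doc_tokens <- function(doc) {
  as.character(unlist(doc_sentences(doc)))
}

#' Level-1 encoder units of a document
#'
#' In `"sentence"` mode the units are the individual sentences (title,
#' abstract, body). In `"section"` mode — the discourse-structure mode used
#' for full-text articles — unit 1 is title+abstract and each body section
#' contributes one unit holding all of its tokens.
#'
#' @param doc a `seqc_document`.
#' @param level `"sentence"` or `"section"`.
#' @param max_unit_tokens per-unit token cap (tail truncation).
#' @param max_units cap on the number of units (tail truncation).
#' @return list of non-empty token vectors.
#' @export
doc_units <- function(doc, level = c("sentence", "section"),
                      max_unit_tokens = NULL, max_units = NULL) {
  level <- match.arg(level)
  if (level == "sentence") {
    units <- doc_sentences(doc)
  } else {
    head_unit <- c(doc$title, unlist(doc$abstract))
    units <- c(
      if (length(head_unit) > 0L) list(as.character(head_unit)) else list(),
      lapply(doc$sections, function(s) as.character(unlist(s$sentences)))
    )
  }
  units <- units[vapply(units, length, 1L) > 0L]
  if (!is.null(max_units) && length(units) > max_units)
    units <- units[seq_len(max_units)]
  if (!is.null(max_unit_tokens))
    units <- lapply(units, function(u)
      if (length(u) > max_unit_tokens) u[seq_len(max_unit_tokens)] else u)
  units
}
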