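# Reading PubMed/PMC-style records and the internal JSONL corpus format.
#
# The XML dialect is a documented simplification of literature records:
#
#   <record source="pubmed|pmc" id="12345">
#     <title>...</title>
#     <abstract>...</abstract>
#     <keyword>...</keyword>*
#     <date>2019-05-01</date>
#     <body>
#       <section title="Methods"> text ... <table>...</table> </section>*
#     </body>
#   </record>
#
# Tables are deleted so only running text survives; reference-like sections
# (references, bibliography, acknowledgments, supplementary) are dropped.

XML_ENTITIES <- c(
  "&lt;" = "<", "&gt;" = ">", "&quot;" = "\"", "&apos;" = "'"
)

#' Replace XML escape sequences with readable characters
#'
#' Handles the five standard entities (`&amp;` `&lt;` `&gt;` `&quot;`
#' `&apos;`) and decimal/hexadecimal numeric character references. Anything
#' else — including malformed entities — is passed through verbatim, and the
#' function is idempotent on text without a raw `&amp;`.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @examples
#' unescape_entities("a &amp; b")
#' @export
unescape_entities <- function(text) {
  vapply(text, function(x) {
    if (is.na(x)) return(NA_character_)
    for (ent in names(XML_ENTITIES)) x <- gsub(ent, XML_ENTITIES[[ent]], x, fixed = TRUE)
    # numeric character references, decimal and hex
    x <- vapply_gsub_ncr(x)
    gsub("&amp;", "&", x, fixed = TRUE)
  }, character(1), USE.NAMES = FALSE)
}

vapply_gsub_ncr <- function(x) {
  m <- gregexpr("&#x?[0-9a-fA-F]+;", x)[[1]]
  if (m[1] == -1L) return(x)
  pieces <- regmatches(x, gregexpr("&#x?[0-9a-fA-F]+;", x))[[1]]
  repl <- vapply(pieces, function(p) {
    body <- sub("^&#", "", sub(";$", "", p))
    code <- if (grepl("^x", body)) strtoi(sub("^x", "", body), 16L) else suppressWarnings(as.integer(body))
    if (is.na(code) || code <= 0L) p else intToUtf8(code)
  }, character(1))
  regmatches(x, gregexpr("&#x?[0-9a-fA-F]+;", x)) <- list(repl)
  x
}

# Section titles treated as non-content and removed on parse.
DROP_SECTION_TITLES <- c("references", "bibliography", "acknowledgments",
                         "acknowledgements", "supplementary")

#' Parse one XML literature record into a document
#'
#' Extracts id, title, abstract, keywords, date and body sections;
#' `<table>` elements are removed wholesale and reference-like sections are
#' excluded, so none of their tokens reach the document.
#'
#' @param xml_text the record XML as a string, or an `xml2` node.
#' @return a [seqc_document()].
#' @export
parse_record <- function(xml_text) {
  node <- if (inherits(xml_text, "xml_node")) xml_text else {
    doc <- tryCatch(xml2::read_xml(xml_text),
                    error = function(e) seqc_abort("parse", "malformed record XML: %s", conditionMessage(e)))
    xml2::xml_root(doc)
  }
  if (xml2::xml_name(node) != "record")
    seqc_abort("parse", "expected a <record> element, got <%s>", xml2::xml_name(node))
  rid <- xml2::xml_attr(node, "id")
  if (is.na(rid) || !nzchar(rid))
    seqc_abort("parse", "record is missing its id attribute")

  # tables never contribute tokens
  xml2::xml_remove(xml2::xml_find_all(node, ".//table"))

  grab <- function(xpath) {
    n <- xml2::xml_find_first(node, xpath)
    if (inherits(n, "xml_missing")) "" else trimws(xml2::xml_text(n))
  }
  title_txt <- unescape_entities(grab("./title"))
  abstract_txt <- unescape_entities(grab("./abstract"))
  if (!nzchar(title_txt) && !nzchar(abstract_txt))
    seqc_abort("parse", "record '%s' has neither title nor abstract", rid)

  keywords <- trimws(xml2::xml_text(xml2::xml_find_all(node, "./keyword")))
  keywords <- unescape_entities(keywords[nzchar(keywords)])

  sections <- list()
  for (sec in xml2::xml_find_all(node, "./body/section")) {
    stitle <- xml2::xml_attr(sec, "title")
    stitle <- if (is.na(stitle)) "" else trimws(stitle)
    if (tolower(stitle) %in% DROP_SECTION_TITLES) next
    sents <- tokenize_sentences(unescape_entities(trimws(xml2::xml_text(sec))))
    if (length(sents) == 0L) next
    sections[[length(sections) + 1L]] <- list(title = stitle, sentences = sents)
  }

  seqc_document(
    doc_id = rid,
    title = tokenize_text(title_txt),
    abstract = tokenize_sentences(abstract_txt),
    sections = sections,
    keywords = keywords,
    date = grab("./date")
  )
}

#' Read every record from XML files
#'
#' Each file may hold a single `<record>` or several wrapped in any root
#' element.
#'
#' @param paths character vector of files or a directory.
#' @return list of [seqc_document()].
#' @export
read_records <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.xml$", full.names = TRUE)
  out <- list()
  for (p in paths) {
    root <- xml2::xml_root(xml2::read_xml(p))
    nodes <- if (xml2::xml_name(root) == "record") list(root)
             else xml2::xml_find_all(root, ".//record")
    for (n in nodes) out[[length(out) + 1L]] <- parse_record(n)
  }
  out
}

#' Default neuroscience topic prefixes
#' @format character vector of five word prefixes.
#' @export
NEURO_PREFIXES <- c("brain", "neuron", "neural", "neuro", "cerebral")

#' Is a document about neuroscience?
#'
#' Word-level, case-insensitive prefix match: `TRUE` iff some token of the
#' title, abstract or body starts with one of the prefixes. The default
#' prefixes are [NEURO_PREFIXES].
#'
#' @param doc a `seqc_document`.
#' @param prefixes non-empty character vector of prefixes.
#' @return logical.
#' @export
is_neuroscience <- function(doc, prefixes = NEURO_PREFIXES) {
  if (length(prefixes) == 0L)
    seqc_abort("config", "at least one prefix is required")
  toks <- tolower(doc_tokens(doc))
  if (length(toks) == 0L) return(FALSE)
  for (p in tolower(prefixes)) {
    if (any(startsWith(toks, p))) return(TRUE)
  }
  FALSE
}

doc_to_json_list <- function(doc) {
  list(
    doc_id = doc$doc_id,
    title = paste(doc$title, collapse = " "),
    abstract = vapply(doc$abstract, paste, character(1), collapse = " "),
    sections = lapply(doc$sections, function(s) list(
      title = s$title,
      sentences = vapply(s$sentences, paste, character(1), collapse = " ")
    )),
    keywords = doc$keywords,
    date = doc$date,
    labels = doc$labels,
    masked = doc$masked
  )
}

json_list_to_doc <- function(x, line = NA_integer_) {
  if (is.null(x$doc_id) || !nzchar(as.character(x$doc_id)[1]))
    seqc_abort("schema", "line %s: missing required field 'doc_id'", line)
  for (f in c("title", "abstract"))
    if (is.null(x[[f]]))
      seqc_abort("schema", "line %s: missing required field '%s'", line, f)
  secs <- lapply(x$sections %||% list(), function(s) list(
    title = as.character(s$title %||% ""),
    sentences = lapply(as.character(unlist(s$sentences %||% character())), tokenize_text)
  ))
  seqc_document(
    doc_id = as.character(x$doc_id),
    title = tokenize_text(as.character(x$title)),
    abstract = lapply(as.character(unlist(x$abstract)), tokenize_text),
    sections = secs,
    keywords = as.character(unlist(x$keywords %||% character())),
    date = as.character(x$date %||% ""),
    labels = if (is.null(x$labels)) NULL else as.character(unlist(x$labels)),
    masked = isTRUE(x$masked)
  )
}

#' Write documents as JSON Lines
#'
#' One JSON object per line with keys `doc_id`, `title`, `abstract` (list of
#' sentence strings), `sections` (list of `{title, sentences}`), `keywords`,
#' `date`, `labels`, `masked`. [read_jsonl()] inverts it field-for-field.
#'
#' @param docs list of `seqc_document`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(d)
    as.character(jsonlite::toJSON(doc_to_json_list(d), auto_unbox = TRUE, null = "null")),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON Lines corpus
#'
#' @param path file written by [write_jsonl()] (or conforming to its schema).
#' @return list of `seqc_document`.
#' @export
read_jsonl <- function(path) {
  if (!file.exists(path)) seqc_abort("io", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) seqc_abort("schema", "line %d: invalid JSON", i))
    out[[i]] <- json_list_to_doc(x, line = i)
  }
  out
}
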