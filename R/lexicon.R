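# Species lexicon: canonical model-organism labels with their surface
# forms, mention finding over token n-grams, mention-based labeling and
# mention masking.

#' The 23 canonical model-organism labels
#' @format character vector, alphabetical.
#' @export
SPECIES_LABELS <- c(
  "Agouti", "Blowfly", "Cat", "Chicken", "Cricket", "Dragonfly",
  "Drosophila melanogaster", "Elegans", "Elephant", "Frog", "Goldfish",
  "Guinea pig", "Human", "Monkey", "Moth", "Mouse", "Rabbit", "Rat",
  "Salamander", "Sheep", "Spiny lobster", "Turtle", "Zebrafish"
)

# Extra classes of the semantic (expert) annotation schema.
#' Extra classes used by semantic annotation
#' @format character vector.
#' @export
SEMANTIC_EXTRA_CLASSES <- c("Cell", "Not applicable", "Others")

read_lexicon_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    seqc_abort("lexicon", "malformed lexicon line: '%s'", lines[which(bad)[1]])
  data.frame(
    canonical = vapply(parts, `[[`, character(1), 1L),
    form = tolower(trimws(vapply(parts, `[[`, character(1), 2L))),
    stringsAsFactors = FALSE
  )
}

#' Build a species lexicon
#'
#' @param entries data frame with columns `canonical`, `form` (forms are
#'   lowercase-normalized here).
#' @param extra_classes optional non-species classes carried alongside
#'   (e.g. [SEMANTIC_EXTRA_CLASSES]); they have no surface forms.
#' @return object of class `seqc_lexicon` with fields `canonicals`,
#'   `forms` (data frame: canonical, form, tokens, n_tokens) and
#'   `extra_classes`.
#' @export
species_lexicon <- function(entries, extra_classes = character()) {
  entries$form <- tolower(trimws(entries$form))
  entries <- unique(entries)
  dup <- entries$form[duplicated(entries$form)]
  if (length(dup) > 0L)
    seqc_abort("lexicon", "surface form '%s' maps to more than one canonical label", dup[1])
  canonicals <- sort(unique(entries$canonical))
  n_forms <- table(entries$canonical)
  if (any(n_forms == 0L) || !setequal(names(n_forms), canonicals))
    seqc_abort("lexicon", "every canonical label needs at least one surface form")
  toks <- lapply(entries$form, function(f) tokenize_text(f))
  if (any(vapply(toks, length, 1L) == 0L))
    seqc_abort("lexicon", "a surface form tokenized to nothing")
  forms <- data.frame(canonical = entries$canonical, form = entries$form,
                      n_tokens = vapply(toks, length, 1L), stringsAsFactors = FALSE)
  forms$tokens <- toks
  # longest-match-first order for the scanner
  forms <- forms[order(-forms$n_tokens, forms$form), ]
  rownames(forms) <- NULL
  structure(list(
    canonicals = canonicals,
    forms = forms,
    extra_classes = as.character(extra_classes),
    # fast lookup: joined lowercase token strings -> canonical
    index = stats::setNames(forms$canonical,
                            vapply(forms$tokens, paste, character(1), collapse = " "))
  ), class = "seqc_lexicon")
}

#' @export
print.seqc_lexicon <- function(x, ...) {
  cat(sprintf("<seqc_lexicon: %d canonical labels, %d surface forms%s>\n",
              length(x$canonicals), nrow(x$forms),
              if (length(x$extra_classes)) sprintf(", +%d extra classes", length(x$extra_classes)) else ""))
  invisible(x)
}

#' Compile the default 23-species lexicon
#'
#' Loads the packaged surface-form inventory (common names, frequent Latin
#' names, plural/variant forms; multiword names kept multiword). Extra
#' aliases may be merged from a TSV of `canonical<TAB>form` pairs; they must
#' extend existing canonicals, never add new ones.
#'
#' @param extra_forms_path optional TSV path with additional aliases.
#' @param include_human_aliases also load the shipped optional
#'   human-related words ("patients", "women", ...). Default `FALSE`.
#' @param extra_classes extra label classes to carry (default none; use
#'   [SEMANTIC_EXTRA_CLASSES] for the expert-annotation schema).
#' @return a `seqc_lexicon` with exactly 23 canonical entries.
#' @export
compile_default_lexicon <- function(extra_forms_path = NULL,
                                    include_human_aliases = FALSE,
                                    extra_classes = character()) {
  entries <- read_lexicon_tsv(system.file("extdata", "species_lexicon.tsv",
                                          package = "seqspecies", mustWork = TRUE))
  if (include_human_aliases) {
    entries <- rbind(entries, read_lexicon_tsv(
      system.file("extdata", "human_aliases.tsv", package = "seqspecies", mustWork = TRUE)))
  }
  if (!is.null(extra_forms_path)) {
    extra <- read_lexicon_tsv(extra_forms_path)
    unknown <- setdiff(unique(extra$canonical), unique(entries$canonical))
    if (length(unknown) > 0L)
      seqc_abort("lexicon", "extra form file introduces unknown canonical '%s'", unknown[1])
    entries <- rbind(entries, extra)
  }
  lex <- species_lexicon(entries, extra_classes = extra_classes)
  stopifnot(length(lex$canonicals) == length(SPECIES_LABELS))
  lex
}

#' Look up the canonical label of a surface form
#'
#' @param lex a `seqc_lexicon`.
#' @param form surface string (any case).
#' @return canonical label, or `NA_character_` when unknown.
#' @export
lexicon_lookup <- function(lex, form) {
  key <- paste(tolower(tokenize_text(form)), collapse = " ")
  out <- lex$index[key]
  unname(out)
}

#' Find species mentions in a document
#'
#' Scans every sentence for case-insensitive surface-form matches over token
#' n-grams, longest match first, left to right, non-overlapping.
#'
#' @param doc a `seqc_document`.
#' @param lex a `seqc_lexicon`.
#' @return data frame with columns `canonical`, `surface`, `unit`
#'   (sentence index into [doc_sentences()]), `start`, `end` (token span,
#'   half-open `[start, end)`), sorted by (unit, start).
#' @export
find_mentions <- function(doc, lex) {
  sents <- doc_sentences(doc)
  max_n <- max(lex$forms$n_tokens)
  res <- list()
  for (ui in seq_along(sents)) {
    toks <- tolower(sents[[ui]])
    len <- length(toks)
    i <- 1L
    while (i <= len) {
      hit_n <- 0L
      hit_canon <- NA_character_
      for (n in seq(min(max_n, len - i + 1L), 1L)) {
        key <- paste(toks[i:(i + n - 1L)], collapse = " ")
        canon <- lex$index[key]
        if (!is.na(canon)) { hit_n <- n; hit_canon <- unname(canon); break }
      }
      if (hit_n > 0L) {
        res[[length(res) + 1L]] <- data.frame(
          canonical = hit_canon,
          surface = paste(sents[[ui]][i:(i + hit_n - 1L)], collapse = " "),
          unit = ui, start = i, end = i + hit_n,
          stringsAsFactors = FALSE)
        i <- i + hit_n
      } else i <- i + 1L
    }
  }
  if (length(res) == 0L)
    return(data.frame(canonical = character(), surface = character(),
                      unit = integer(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Mention-based species labels of a document
#'
#' The mention-based annotation standard: every species whose surface form
#' occurs in the document becomes a label. The document is not modified.
#'
#' @inheritParams find_mentions
#' @return sorted character vector of canonical labels (possibly empty).
#' @export
annotate_mention_labels <- function(doc, lex) {
  sort(unique(find_mentions(doc, lex)$canonical))
}

#' Annotate a whole corpus with mention-based labels
#' @param docs list of `seqc_document`.
#' @param lex a `seqc_lexicon`.
#' @return the documents with `$labels` filled in.
#' @export
annotate_corpus <- function(docs, lex) {
  lapply(docs, function(d) { d$labels <- annotate_mention_labels(d, lex); d })
}

#' Mask species mentions
#'
#' Every mention span is replaced by the single token [SPECIES_MASK]
#' (multiword mentions collapse to one mask token) and the `masked` flag is
#' set. Labels are retained. The input document is unmodified;
#' `find_mentions()` on the result finds nothing.
#'
#' @inheritParams find_mentions
#' @return a new masked `seqc_document`.
#' @export
mask_mentions <- function(doc, lex) {
  men <- find_mentions(doc, lex)
  sents <- doc_sentences(doc)
  if (nrow(men) > 0L) {
    for (ui in unique(men$unit)) {
      spans <- men[men$unit == ui, , drop = FALSE]
      spans <- spans[order(-spans$start), , drop = FALSE]  # right-to-left keeps indices valid
      s <- sents[[ui]]
      for (k in seq_len(nrow(spans))) {
        left <- if (spans$start[k] > 1L) s[seq_len(spans$start[k] - 1L)] else character()
        right <- if (spans$end[k] <= length(s)) s[seq(spans$end[k], length(s))] else character()
        s <- c(left, SPECIES_MASK, right)
      }
      sents[[ui]] <- s
    }
  }
  # write the edited sentences back into the document structure
  out <- doc
  idx <- 1L
  if (length(doc$title) > 0L) { out$title <- sents[[idx]]; idx <- idx + 1L }
  if (length(doc$abstract) > 0L) {
    out$abstract <- sents[seq(idx, idx + length(doc$abstract) - 1L)]
    idx <- idx + length(doc$abstract)
  }
  for (si in seq_along(doc$sections)) {
    ns <- length(doc$sections[[si]]$sentences)
    if (ns > 0L) {
      out$sections[[si]]$sentences <- sents[seq(idx, idx + ns - 1L)]
      idx <- idx + ns
    }
  }
  out$masked <- TRUE
  out
}

#' Mask a whole corpus
#' @inheritParams annotate_corpus
#' @return list of masked documents.
#' @export
mask_corpus <- function(docs, lex) lapply(docs, mask_mentions, lex = lex)
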