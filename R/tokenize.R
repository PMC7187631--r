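# Tokenisation and sentence splitting.
#
# The rules are deliberately simple and deterministic: whitespace split,
# then strip leading/trailing punctuation from each token while keeping
# internal punctuation (hyphens, dots in "5-HT", "N171-82Q", ...) and the
# original case. Case folding is left to consumers (the lexicon matcher and
# the neuroscience filter lowercase on their side).

#' Mask symbol used when species mentions are hidden
#'
#' Documents whose species mentions have been masked carry this single token
#' in place of each mention. The tokenizer treats it as an atom (its
#' asterisks are never stripped) so masked corpora survive text round-trips.
#'
#' @format A length-one character vector.
#' @export
SPECIES_MASK <- "*SPECIES*"

#' Tokenize a string
#'
#' Whitespace split followed by removal of leading/trailing punctuation.
#' Tokens that become empty (pure punctuation) are dropped. Token case is
#' preserved. The mask symbol [SPECIES_MASK] is kept verbatim.
#'
#' @param text a character vector; elements are concatenated with spaces.
#' @return character vector of tokens (possibly empty).
#' @examples
#' tokenize_text("Neurons fire (fast).")
#' @export
tokenize_text <- function(text) {
  if (length(text) == 0L) return(character())
  text <- paste(text, collapse = " ")
  raw <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  if (length(raw) == 0L || identical(raw, "")) return(character())
  keep <- raw == SPECIES_MASK
  stripped <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", raw)
  stripped[keep] <- SPECIES_MASK
  stripped[nzchar(stripped)]
}

# Abbreviations that must not end a sentence. Compared case-sensitively
# against the word preceding a period.
SENTENCE_ABBREV <- c(
  "al", "et", "Fig", "Figs", "fig", "e.g", "i.e", "cf", "vs", "Dr", "Mr",
  "Mrs", "Ms", "Prof", "St", "No", "approx", "Eq", "Eqs", "ca"
)

#' Split raw text into sentences
#'
#' Rule-based splitter: a sentence boundary is a run of `.`, `!` or `?`
#' followed by whitespace and an uppercase letter or digit, unless the word
#' immediately before the terminator is a known abbreviation
#' ("et al.", "Fig.", ...). Deterministic by construction.
#'
#' @param text single string.
#' @return character vector of sentence strings (trimmed, non-empty).
#' @export
split_sentences <- function(text) {
  if (!is_string(text) || !nzchar(trimws(text))) return(character())
  text <- trimws(text)
  m <- gregexpr("[.!?]+(?=[[:space:]]+[A-Z0-9])", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(text)
  cuts <- integer()
  for (k in seq_along(m)) {
    pos <- m[k]
    prefix <- substr(text, 1L, pos - 1L)
    prev <- regmatches(prefix, regexpr("[[:alnum:].]+$", prefix))
    prev <- if (length(prev)) sub("\\.$", "", prev) else ""
    if (!(prev %in% SENTENCE_ABBREV)) {
      cuts <- c(cuts, pos + attr(m, "match.length")[k] - 1L)
    }
  }
  if (length(cuts) == 0L) return(text)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(text))
  out <- trimws(substring(text, starts, ends))
  out[nzchar(out)]
}

#' Split text into tokenized sentences
#'
#' Convenience composition of [split_sentences()] and [tokenize_text()];
#' sentences that tokenize to nothing are dropped.
#'
#' @param text single string.
#' @return list of character vectors, one per sentence.
#' @export
tokenize_sentences <- function(text) {
  sents <- lapply(split_sentences(text), tokenize_text)
  sents[vapply(sents, length, 1L) > 0L]
}
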