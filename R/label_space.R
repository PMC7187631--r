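# Label vocabulary and virtual label sequences.
#
# The decoder emits species labels as a sequence. The label alphabet is
# ordered by descending training-set frequency (frequent labels first); a
# label set becomes a virtual sequence by sorting it in vocabulary order and
# wrapping it in BOS/EOS.

BOS <- "<BOS>"
EOS <- "<EOS>"

#' Build the frequency-ordered label vocabulary
#'
#' Labels are ordered by descending frequency over the training label sets;
#' ties break alphabetically. Labels from `all_labels` that never occur get
#' frequency 0 and are appended alphabetically, so the alphabet can always
#' cover the full lexicon.
#'
#' @param label_sets list of character vectors (one per training document).
#' @param all_labels optional universe of labels to cover.
#' @return object of class `seqc_label_vocab`: `labels` (ordered),
#'   `frequencies`, `bos_index`, `eos_index`, and `size` (m, excluding
#'   BOS/EOS).
#' @export
build_label_vocab <- function(label_sets, all_labels = NULL) {
  if (length(label_sets) == 0L)
    seqc_abort("value", "at least one training document is required")
  observed <- unlist(lapply(label_sets, function(s) unique(as.character(s))))
  counts <- table(observed)
  universe <- sort(unique(c(names(counts), all_labels)))
  if (length(universe) == 0L)
    seqc_abort("value", "no labels found and no label universe given")
  if (any(universe %in% c(BOS, EOS)))
    seqc_abort("value", "label names may not collide with BOS/EOS")
  freq <- stats::setNames(rep(0L, length(universe)), universe)
  freq[names(counts)] <- as.integer(counts)
  ord <- order(-freq, names(freq))
  labels <- names(freq)[ord]
  structure(list(
    labels = labels,
    frequencies = freq[ord],
    size = length(labels),
    bos_index = length(labels) + 1L,
    eos_index = length(labels) + 2L
  ), class = "seqc_label_vocab")
}

#' @export
print.seqc_label_vocab <- function(x, ...) {
  cat(sprintf("<seqc_label_vocab: m=%d labels [%s%s]>\n", x$size,
              paste(utils::head(x$labels, 5), collapse = ", "),
              if (x$size > 5) ", ..." else ""))
  invisible(x)
}

label_index <- function(vocab, labels) {
  idx <- match(labels, vocab$labels)
  if (anyNA(idx))
    seqc_abort("key", "unknown label '%s'", labels[which(is.na(idx))[1]])
  idx
}

#' Convert a label set to a virtual label sequence
#'
#' The interior order is the vocabulary order (frequency-descending),
#' independent of the input order; BOS/EOS are prepended/appended.
#'
#' @param label_set character vector (a set; duplicates ignored).
#' @param vocab a [build_label_vocab()] result.
#' @return character vector `c(BOS, labels..., EOS)`.
#' @export
to_label_sequence <- function(label_set, vocab) {
  label_set <- unique(as.character(label_set))
  idx <- sort(label_index(vocab, label_set))
  c(BOS, vocab$labels[idx], EOS)
}

#' Recover the label set from a sequence
#'
#' Takes the labels strictly between BOS (if present) and the first EOS;
#' anything after EOS is ignored. Order is discarded — evaluation is on
#' sets.
#'
#' @param seq character vector of sequence tokens.
#' @return sorted character vector of unique labels.
#' @export
from_label_sequence <- function(seq) {
  seq <- as.character(seq)
  seq <- seq[seq != BOS]
  eos_at <- which(seq == EOS)
  if (length(eos_at) > 0L) seq <- seq[seq_len(eos_at[1] - 1L)]
  sort(unique(seq))
}

#' Serialize a label vocabulary to JSON
#' @param vocab a `seqc_label_vocab`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_label_vocab <- function(vocab, path) {
  jsonlite::write_json(
    list(labels = vocab$labels, frequencies = as.list(vocab$frequencies)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a label vocabulary from JSON
#' @param path file written by [write_label_vocab()].
#' @return a `seqc_label_vocab`.
#' @export
read_label_vocab <- function(path) {
  x <- jsonlite::fromJSON(path)
  labels <- as.character(x$labels)
  freq <- stats::setNames(as.integer(unlist(x$frequencies)[labels]), labels)
  structure(list(labels = labels, frequencies = freq, size = length(labels),
                 bos_index = length(labels) + 1L, eos_index = length(labels) + 2L),
            class = "seqc_label_vocab")
}
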