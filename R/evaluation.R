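# Multi-label evaluation: Hamming loss, micro-/macro-F1 and per-document
# P/R/F1. Predictions and gold are compared as sets; label order never
# matters.
#
# Degenerate-case conventions (stated because they are conventions):
# class-level P/R/F1 use 0/0 -> 0; a document with empty gold AND empty
# prediction scores P=R=F1=1; macro-F1 averages over the full vocabulary.

label_matrix <- function(sets, labels) {
  out <- matrix(0L, nrow = length(sets), ncol = length(labels),
                dimnames = list(NULL, labels))
  for (i in seq_along(sets)) {
    s <- unique(as.character(sets[[i]]))
    if (length(s) > 0L) {
      idx <- match(s, labels)
      if (anyNA(idx))
        seqc_abort("value", "label '%s' not in vocabulary", s[which(is.na(idx))[1]])
      out[i, idx] <- 1L
    }
  }
  out
}

check_aligned <- function(pred_sets, gold_sets) {
  if (length(pred_sets) != length(gold_sets))
    seqc_abort("value", "prediction and gold lists differ in length (%d vs %d)",
               length(pred_sets), length(gold_sets))
  if (length(pred_sets) == 0L)
    seqc_abort("value", "cannot evaluate zero documents")
}

as_label_universe <- function(vocab) {
  if (inherits(vocab, "seqc_label_vocab")) vocab$labels else as.character(vocab)
}

#' Hamming loss
#'
#' Fraction of wrong label slots: the mean XOR between the binary
#' prediction and gold indicator matrices over all documents and all
#' vocabulary labels. 0 for an ideal classifier, 1 when every slot is
#' wrong.
#'
#' @param pred_sets,gold_sets lists of label sets (character vectors), same
#'   length and order.
#' @param vocab a `seqc_label_vocab` or a character vector of labels.
#' @return a fraction in `[0, 1]`.
#' @export
hamming_loss <- function(pred_sets, gold_sets, vocab) {
  check_aligned(pred_sets, gold_sets)
  labels <- as_label_universe(vocab)
  P <- label_matrix(pred_sets, labels)
  G <- label_matrix(gold_sets, labels)
  mean(P != G)
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Micro-averaged precision, recall and F1
#'
#' True/false positives and false negatives are pooled globally over all
#' documents and labels before computing P, R and their harmonic mean.
#'
#' @inheritParams hamming_loss
#' @return named numeric: `precision`, `recall`, `f1`.
#' @export
micro_f1 <- function(pred_sets, gold_sets) {
  check_aligned(pred_sets, gold_sets)
  tp <- fp <- fn <- 0L
  for (i in seq_along(pred_sets)) {
    p <- unique(as.character(pred_sets[[i]]))
    g <- unique(as.character(gold_sets[[i]]))
    tp <- tp + length(intersect(p, g))
    fp <- fp + length(setdiff(p, g))
    fn <- fn + length(setdiff(g, p))
  }
  prf(tp, fp, fn)
}

per_class_prf <- function(pred_sets, gold_sets, labels) {
  P <- label_matrix(pred_sets, labels)
  G <- label_matrix(gold_sets, labels)
  out <- t(vapply(seq_along(labels), function(j) {
    tp <- sum(P[, j] == 1L & G[, j] == 1L)
    fp <- sum(P[, j] == 1L & G[, j] == 0L)
    fn <- sum(P[, j] == 0L & G[, j] == 1L)
    c(prf(tp, fp, fn), support = sum(G[, j]))
  }, c(precision = 0, recall = 0, f1 = 0, support = 0)))
  data.frame(label = labels, out, row.names = NULL, stringsAsFactors = FALSE)
}

#' Macro-averaged F1
#'
#' Unweighted mean of per-class F1 over every vocabulary label; a class
#' with neither gold nor predicted positives contributes F1 = 0.
#'
#' @inheritParams hamming_loss
#' @return a fraction in `[0, 1]`.
#' @export
macro_f1 <- function(pred_sets, gold_sets, vocab) {
  check_aligned(pred_sets, gold_sets)
  mean(per_class_prf(pred_sets, gold_sets, as_label_universe(vocab))$f1)
}

#' Document-averaged precision, recall and F1
#'
#' Computes set P/R/F1 per document, then takes arithmetic means. A
#' document with empty gold and empty prediction scores 1/1/1.
#'
#' @inheritParams hamming_loss
#' @return named numeric: `precision`, `recall`, `f1`.
#' @export
per_document_prf <- function(pred_sets, gold_sets) {
  check_aligned(pred_sets, gold_sets)
  rows <- t(vapply(seq_along(pred_sets), function(i) {
    p <- unique(as.character(pred_sets[[i]]))
    g <- unique(as.character(gold_sets[[i]]))
    if (length(p) == 0L && length(g) == 0L)
      return(c(precision = 1, recall = 1, f1 = 1))
    tp <- length(intersect(p, g))
    prf(tp, length(p) - tp, length(g) - tp)
  }, c(precision = 0, recall = 0, f1 = 0)))
  colMeans(rows)
}

#' Full multi-label evaluation report
#'
#' @param predictions named list: `doc_id -> predicted label set`, or an
#'   unnamed list aligned with `gold`.
#' @param gold named list: `doc_id -> gold label set` (names required when
#'   `predictions` is named).
#' @param vocab a `seqc_label_vocab` or character vector of labels.
#' @return object of class `seqc_metrics`: `hamming`, `micro`
#'   (precision/recall/f1), `macro_f1`, `per_document`
#'   (precision/recall/f1), `per_class` (data frame), `n_documents`.
#' @export
evaluate_predictions <- function(predictions, gold, vocab) {
  if (!is.null(names(predictions)) && !is.null(names(gold))) {
    missing_ids <- setdiff(names(gold), names(predictions))
    if (length(missing_ids) > 0L)
      seqc_abort("key", "no prediction for document '%s'", missing_ids[1])
    predictions <- predictions[names(gold)]
  }
  check_aligned(predictions, gold)
  labels <- as_label_universe(vocab)
  structure(list(
    hamming = hamming_loss(predictions, gold, labels),
    micro = micro_f1(predictions, gold),
    macro_f1 = macro_f1(predictions, gold, labels),
    per_document = per_document_prf(predictions, gold),
    per_class = per_class_prf(predictions, gold, labels),
    n_documents = length(gold)
  ), class = "seqc_metrics")
}

#' @export
print.seqc_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "Multi-label evaluation over %d documents\n",
    "  Hamming loss : %.4f\n",
    "  micro-P/R/F1 : %.4f / %.4f / %.4f\n",
    "  macro-F1     : %.4f\n",
    "  per-doc P/R/F1: %.4f / %.4f / %.4f\n"),
    x$n_documents, x$hamming,
    x$micro["precision"], x$micro["recall"], x$micro["f1"],
    x$macro_f1,
    x$per_document["precision"], x$per_document["recall"], x$per_document["f1"]))
  invisible(x)
}
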