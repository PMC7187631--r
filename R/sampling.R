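# Full-category sampling (FCS) and corpus partitioning.
#
# FCS builds class-balanced datasets from a large labeled candidate pool:
# shuffle, take n candidates, then scan once, admitting a document while at
# least one of its labels is still below the class support degree s. The
# shuffle prevents oversampling of sparse classes; the support cap bounds
# every class's tally.

#' Sampling configuration
#'
#' @param n number of shuffled candidate documents considered (default
#'   50000).
#' @param support class support degree `s`: per-class cap on sampled
#'   documents (default 400); `Inf` accepts every labeled candidate.
#' @param seed shuffle seed.
#' @return list of class `seqc_sample_config`.
#' @export
sample_config <- function(n = 50000L, support = 400L, seed = 1L) {
  if (!is.numeric(n) || n < 1) seqc_abort("config", "'n' must be >= 1")
  if (!is.numeric(support) || support < 1) seqc_abort("config", "'support' must be >= 1")
  structure(list(n = n, support = support, seed = as.integer(seed)),
            class = "seqc_sample_config")
}

#' Full-category sampling
#'
#' Single-pass class-capped sampling. The candidate pool is the corpus
#' shuffled under `cfg$seed`, truncated to `cfg$n`. Scanning in order, a
#' document is added when any of its labels has a running tally below
#' `cfg$support`; each such label's tally is incremented (only while below
#' the cap), and a document is added at most once. Documents with no labels
#' are never added. Output preserves scan order.
#'
#' @param corpus list of labeled `seqc_document` (each `$labels` may be
#'   empty but must not be `NULL`; unlabeled docs are simply never sampled).
#' @param cfg a [sample_config()].
#' @param shuffle set `FALSE` to keep the given order (used for hand
#'   traces).
#' @return list: `samples` (the selected documents, scan order) and
#'   `tallies` (named integer vector of per-class counts).
#' @export
full_category_sample <- function(corpus, cfg = sample_config(), shuffle = TRUE) {
  if (length(corpus) == 0L)
    return(list(samples = list(), tallies = integer()))
  ord <- if (shuffle) with_seed(cfg$seed, sample.int(length(corpus))) else seq_along(corpus)
  cand <- corpus[ord]
  if (length(cand) > cfg$n) cand <- cand[seq_len(cfg$n)]
  tallies <- new.env(parent = emptyenv())
  samples <- vector("list", length(cand))
  kept <- 0L
  for (d in cand) {
    tags <- d$labels %||% character()
    added <- FALSE
    for (tg in tags) {
      cur <- get0(tg, envir = tallies, ifnotfound = 0L)
      if (cur < cfg$support) {
        assign(tg, cur + 1L, envir = tallies)
        if (!added) { kept <- kept + 1L; samples[[kept]] <- d }
        added <- TRUE
      }
    }
  }
  tl <- unlist(as.list(tallies)) %||% integer()
  list(samples = samples[seq_len(kept)],
       tallies = if (length(tl)) tl[order(names(tl))] else integer())
}

#' Remove documents that also appear in another corpus
#'
#' Identity is by `doc_id`; order of the primary corpus is preserved.
#'
#' @param primary,secondary lists of `seqc_document`.
#' @return the primary corpus without overlapping documents.
#' @export
remove_overlap <- function(primary, secondary) {
  sec_ids <- vapply(secondary, `[[`, character(1), "doc_id")
  keep <- !vapply(primary, function(d) d$doc_id %in% sec_ids, logical(1))
  primary[keep]
}

#' Deterministic train/dev/test split
#'
#' Shuffles under `seed` and cuts into three parts whose sizes are the
#' rounded ratios (the last part absorbs rounding remainder).
#'
#' @param docs list of documents.
#' @param ratios numeric triple summing to 1.
#' @param seed integer.
#' @return list with elements `train`, `dev`, `test` (disjoint, covering
#'   `docs`).
#' @export
split_corpus <- function(docs, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9)
    seqc_abort("value", "'ratios' must be three non-negative numbers summing to 1")
  n <- length(docs)
  ord <- with_seed(seed, sample.int(max(n, 1L)))[seq_len(n)]
  n_train <- round(ratios[1] * n)
  n_dev <- round(ratios[2] * n)
  n_dev <- min(n_dev, n - n_train)
  idx_train <- ord[seq_len(n_train)]
  idx_dev <- if (n_dev > 0) ord[n_train + seq_len(n_dev)] else integer()
  idx_test <- setdiff(ord, c(idx_train, idx_dev))
  list(train = docs[idx_train], dev = docs[idx_dev], test = docs[idx_test])
}
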