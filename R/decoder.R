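# Label-sequence decoder with hierarchical attentive decoding (HAD).
#
# Per step t (following the update order of the defining equations
# literally): the attention query is the PRE-update hidden state h_{t-1};
# it yields the context c_t, while the LSTM input consumes the previous
# step's context c_{t-1} concatenated with the previous label's embedding.
# Unit weights beta scale word-level scores before one global softmax over
# all (unit, word) pairs; the logits are masked so an already-predicted
# label has probability exactly zero. EOS is never masked.

# Attention over an encoded document. h_prev: 1 x tau node. Returns the
# context node plus numeric alpha (per word) and beta (per unit) maps, each
# summing to 1 in every mode.
attend_graph <- function(tape, p, enc, h_prev, mode) {
  uw <- enc$unit_of_word
  n_per_unit <- tabulate(uw, nbins = enc$n_units)
  if (mode == "no_attention") {
    tau <- ncol(h_prev$value)
    ctx <- ad_leaf(tape, matrix(0, 1L, tau))
    beta <- rep(1 / enc$n_units, enc$n_units)
    return(list(ctx = ctx, alpha = beta[uw] / n_per_unit[uw], beta = beta))
  }
  proj_q <- ad_add(tape, ad_matmul(tape, h_prev, p$att_W2), p$att_b)  # 1 x tau
  score_of <- function(H)
    ad_matmul(tape, ad_tanh(tape, ad_add(tape, ad_matmul(tape, H, p$att_W1), proj_q)),
              p$att_v)
  if (mode == "no_w_att") {
    beta <- ad_softmax_col(tape, score_of(enc$unit_vectors))
    ctx <- ad_matmul(tape, ad_transpose(tape, beta), enc$unit_vectors)
    bv <- as.vector(beta$value)
    return(list(ctx = ctx, alpha = bv[uw] / n_per_unit[uw], beta = bv))
  }
  w_scores <- score_of(enc$word_states)  # N x 1
  if (mode == "HAD") {
    beta <- ad_softmax_col(tape, score_of(enc$unit_vectors))
    scaled <- ad_mul(tape, ad_rows(tape, beta, uw), w_scores)
    alpha <- ad_softmax_col(tape, scaled)
    bv <- as.vector(beta$value)
  } else {  # no_s_att: word attention without the unit-level weighting
    alpha <- ad_softmax_col(tape, w_scores)
    bv <- as.vector(rowsum(alpha$value, group = uw))
  }
  ctx <- ad_matmul(tape, ad_transpose(tape, alpha), enc$word_states)
  list(ctx = ctx, alpha = as.vector(alpha$value), beta = bv)
}

# One decoder LSTM cell step built from elementary ops. x: 1 x 2tau.
dec_cell <- function(tape, p, x, h_prev, c_prev) {
  tau <- ncol(h_prev$value)
  z <- ad_add(tape, ad_add(tape, ad_matmul(tape, x, p$dec_Wx),
                           ad_matmul(tape, h_prev, p$dec_Wh)), p$dec_b)
  i <- ad_sigmoid(tape, ad_cols(tape, z, seq_len(tau)))
  f <- ad_sigmoid(tape, ad_cols(tape, z, tau + seq_len(tau)))
  g <- ad_tanh(tape, ad_cols(tape, z, 2L * tau + seq_len(tau)))
  o <- ad_sigmoid(tape, ad_cols(tape, z, 3L * tau + seq_len(tau)))
  cell <- ad_add(tape, ad_mul(tape, f, c_prev), ad_mul(tape, i, g))
  list(h = ad_mul(tape, o, ad_tanh(tape, cell)), cell = cell)
}

# Fresh decoder state over an encoded document: h0 = document vector,
# cell0 = 0, c0 = 0, nothing predicted.
decoder_init <- function(enc) {
  tau <- ncol(enc$doc_vector$value)
  list(t = 0L,
       h = enc$doc_vector,
       cell = ad_leaf(enc$tape, matrix(0, 1L, tau)),
       ctx = ad_leaf(enc$tape, matrix(0, 1L, tau)),
       predicted = integer(),
       finished = FALSE)
}

# Output-alphabet mask from the set of already-predicted label indices.
# length m+1; EOS (m+1) is never masked.
repeat_mask <- function(m, predicted) {
  mask <- logical(m + 1L)
  mask[predicted] <- TRUE
  mask
}

#' Advance the decoder by one step
#'
#' Computes the attention context from the pre-update hidden state, feeds
#' the previous label's embedding concatenated with the previous context
#' through the decoder LSTM, and returns the masked next-label
#' distribution. Already-predicted labels have probability exactly 0; EOS
#' is always available.
#'
#' @param model a `seqc_model`.
#' @param enc an [encode_document()] result.
#' @param state a decoder state (from `decoder_init` via previous steps or
#'   a fresh encoding).
#' @param prev_index the previous output: a label index (1..m), `m + 1`
#'   for EOS, or `NULL` at the first step (BOS).
#' @param training apply dropout to the decoder input.
#' @return list: `state` (advanced), `dist` (named probability vector over
#'   labels + EOS), `alpha`, `beta` (attention maps).
#' @export
decoder_step <- function(model, enc, state = NULL, prev_index = NULL,
                         training = FALSE) {
  if (is.null(state)) state <- decoder_init(enc)
  if (state$finished)
    seqc_abort("state", "decoder already emitted EOS")
  tape <- enc$tape
  p <- enc$params
  m <- model$label_vocab$size
  rows <- spec_rows(model)
  prev_row <- if (is.null(prev_index)) rows$bos else as.integer(prev_index)

  att <- attend_graph(tape, p, enc, state$h, model$decoder_cfg$mode)
  x <- ad_hcat(tape, ad_rows(tape, p$spec_emb, prev_row), state$ctx)
  x <- ad_dropout(tape, x, model$encoder_cfg$dropout, training)
  cellout <- dec_cell(tape, p, x, state$h, state$cell)
  logits <- ad_add(tape, ad_matmul(tape, cellout$h, p$out_W), p$out_b)
  mask <- repeat_mask(m, state$predicted)
  dist <- masked_softmax(as.vector(logits$value), mask)
  names(dist) <- c(model$label_vocab$labels, EOS)

  new_state <- list(t = state$t + 1L, h = cellout$h, cell = cellout$cell,
                    ctx = att$ctx, predicted = state$predicted,
                    finished = FALSE, logits = logits, mask = mask)
  list(state = new_state, dist = dist, alpha = att$alpha, beta = att$beta)
}

# Record an emitted symbol on a state returned by decoder_step().
state_emit <- function(state, index, m) {
  if (index <= m) state$predicted <- c(state$predicted, as.integer(index))
  else state$finished <- TRUE
  state
}

finish_result <- function(model, enc, seq_idx, logps, dists, alphas, betas) {
  m <- model$label_vocab$size
  labels <- model$label_vocab$labels[seq_idx[seq_idx <= m]]
  structure(list(
    doc_id = enc$doc_id,
    labels = labels,
    sequence = c(BOS, labels, if (any(seq_idx == m + 1L)) EOS),
    log_prob = sum(logps),
    step_log_probs = logps,
    step_distributions = dists,
    attention = Map(function(a, b) list(alpha = a, beta = b), alphas, betas),
    tokens = enc$tokens,
    unit_of_word = enc$unit_of_word
  ), class = "seqc_decode_result")
}

#' @export
print.seqc_decode_result <- function(x, ...) {
  cat(sprintf("<seqc_decode_result %s: {%s} log-prob %.4f>\n",
              x$doc_id, paste(x$labels, collapse = ", "), x$log_prob))
  invisible(x)
}

#' Greedy decoding
#'
#' Repeatedly takes the argmax of the masked distribution until EOS or
#' until all m labels have been emitted (after which only EOS remains).
#'
#' @param model a `seqc_model`.
#' @param enc an encoded document, or a `seqc_document` (encoded on the
#'   fly).
#' @return a `seqc_decode_result` with per-step distributions and
#'   attention maps.
#' @export
greedy_decode <- function(model, enc) {
  if (inherits(enc, "seqc_document")) enc <- encode_document(model, enc)
  m <- model$label_vocab$size
  state <- NULL; prev <- NULL
  seq_idx <- integer(); logps <- numeric()
  dists <- list(); alphas <- list(); betas <- list()
  for (t in seq_len(m + 1L)) {
    st <- decoder_step(model, enc, state, prev)
    k <- which.max(st$dist)
    seq_idx <- c(seq_idx, k)
    logps <- c(logps, log(st$dist[[k]]))
    dists[[t]] <- st$dist; alphas[[t]] <- st$alpha; betas[[t]] <- st$beta
    state <- state_emit(st$state, k, m)
    if (k == m + 1L) break
    prev <- k
  }
  finish_result(model, enc, seq_idx, logps, dists, alphas, betas)
}

#' Beam-search decoding
#'
#' Keeps the `width` highest accumulated-log-probability partial sequences;
#' beams that emit EOS are frozen and compete on total log-probability (no
#' length normalisation). Ties break toward shorter sequences, then
#' lexicographically by label names.
#'
#' @inheritParams greedy_decode
#' @param width beam width (default from the decoder configuration).
#' @return the best complete `seqc_decode_result`.
#' @export
beam_search <- function(model, enc, width = NULL) {
  if (inherits(enc, "seqc_document")) enc <- encode_document(model, enc)
  width <- as.integer(width %||% model$decoder_cfg$beam_width)
  if (width < 1) seqc_abort("config", "beam width must be >= 1")
  m <- model$label_vocab$size

  new_beam <- function(state, prev, seq_idx, logp, logps, dists, alphas, betas)
    list(state = state, prev = prev, seq_idx = seq_idx, logp = logp,
         logps = logps, dists = dists, alphas = alphas, betas = betas,
         finished = !is.null(state) && state$finished)
  beams <- list(new_beam(NULL, NULL, integer(), 0, numeric(), list(), list(), list()))

  sym_names <- c(model$label_vocab$labels, EOS)
  beam_key <- function(b) paste(sym_names[b$seq_idx], collapse = "")
  select_top <- function(pool, k) {
    logp <- vapply(pool, `[[`, 0, "logp")
    lens <- vapply(pool, function(b) sum(b$seq_idx <= m), 0)
    keys <- vapply(pool, beam_key, "")
    pool[order(-logp, lens, keys)][seq_len(min(k, length(pool)))]
  }

  for (t in seq_len(m + 1L)) {
    if (all(vapply(beams, `[[`, TRUE, "finished"))) break
    pool <- list()
    for (b in beams) {
      if (b$finished) { pool[[length(pool) + 1L]] <- b; next }
      st <- decoder_step(model, enc, b$state, b$prev)
      open <- which(st$dist > 0)
      for (k in open) {
        nst <- state_emit(st$state, k, m)
        pool[[length(pool) + 1L]] <- new_beam(
          nst, if (k <= m) k else NULL,
          c(b$seq_idx, k), b$logp + log(st$dist[[k]]),
          c(b$logps, log(st$dist[[k]])),
          c(b$dists, list(st$dist)), c(b$alphas, list(st$alpha)),
          c(b$betas, list(st$beta)))
      }
    }
    beams <- select_top(pool, width)
  }
  done <- Filter(function(b) b$finished, beams)
  if (length(done) == 0L) done <- beams  # cannot happen: EOS forced at t = m+1
  best <- select_top(done, 1L)[[1L]]
  finish_result(model, enc, best$seq_idx, best$logps, best$dists,
                best$alphas, best$betas)
}

#' Export per-step attention maps aligned to document tokens
#'
#' Produces a JSON-ready report mapping each predicted label (and EOS) to a
#' weight per document token — the spans of interest the decoder looked at
#' for that prediction.
#'
#' @param result a `seqc_decode_result`.
#' @param doc the `seqc_document` the result was produced from.
#' @param model the model used (for truncation settings).
#' @return list: `doc_id`, `tokens`, and `steps`, each step holding
#'   `label`, `token_weights` (sums to 1) and `unit_weights` (sums to 1).
#' @export
export_attention <- function(result, doc, model) {
  ec <- model$encoder_cfg
  toks <- unlist(doc_units(doc, ec$level1_unit, ec$max_unit_tokens, ec$max_units))
  if (length(toks) != length(result$tokens) || !all(toks == result$tokens))
    seqc_abort("alignment", "document tokens do not match the decode result")
  steps <- result$sequence[-1L]  # drop BOS; keep labels then EOS
  out_steps <- vector("list", length(result$attention))
  for (t in seq_along(result$attention)) {
    out_steps[[t]] <- list(
      label = steps[t],
      token_weights = as.numeric(result$attention[[t]]$alpha),
      unit_weights = as.numeric(result$attention[[t]]$beta))
  }
  list(doc_id = result$doc_id, tokens = as.character(toks), steps = out_steps)
}

#' Predict label sets for a corpus
#'
#' @param model a `seqc_model`.
#' @param docs list of `seqc_document`.
#' @param beam beam width; `1` uses greedy decoding.
#' @return named list `doc_id -> character vector of predicted labels`.
#' @export
predict_corpus <- function(model, docs, beam = 1L) {
  out <- lapply(docs, function(d) {
    res <- if (beam <= 1L) greedy_decode(model, d) else beam_search(model, d, beam)
    sort(res$labels)
  })
  stats::setNames(out, vapply(docs, `[[`, character(1), "doc_id"))
}
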