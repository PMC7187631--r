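# Hierarchical document encoding.
#
# Level 1: a shared bidirectional LSTM runs over every sentence/section
# (all units in one masked batch); each token gets a contextual state (the
# concatenation of both directions, dimension tau) and each unit gets a
# summary vector (concatenated final states). Level 2: a second
# bidirectional LSTM over the unit vectors yields the document vector.

# Wrap model parameters (trainable and fixed) as tape leaves.
wrap_params <- function(tape, model) {
  nodes <- lapply(model$params, function(v) ad_leaf(tape, v))
  for (nm in names(model$fixed)) nodes[[nm]] <- ad_leaf(tape, model$fixed[[nm]])
  nodes
}

# Character feature vectors for a set of token strings -> node (n x c_out).
char_features <- function(tape, p, model, tokens) {
  ec <- model$encoder_cfg
  chars <- attr(model$params$char_emb, "chars")
  uniq <- unique(tokens)
  per_tok <- vector("list", length(uniq))
  zero_row <- ad_leaf(tape, matrix(0, 1L, ec$char_dim))
  for (k in seq_along(uniq)) {
    cs <- strsplit(uniq[k], "")[[1]]
    ids <- match(cs, chars)
    ids[is.na(ids)] <- 0L
    ids <- ids + 1L  # row 1 of char_emb is the unknown character
    C <- ad_rows(tape, p$char_emb, ids)
    n <- length(ids)
    if (ec$char_mode == "cnn") {
      padded <- ad_vcat(tape, list(zero_row, C, zero_row))  # (n+2) x c
      win <- ad_hcat(tape, ad_hcat(tape,
               ad_rows(tape, padded, seq_len(n)),
               ad_rows(tape, padded, seq_len(n) + 1L)),
               ad_rows(tape, padded, seq_len(n) + 2L))      # n x 3c
      conv <- ad_tanh(tape, ad_add(tape, ad_matmul(tape, win, p$char_Wc), p$char_bc))
      per_tok[[k]] <- ad_colmax(tape, conv)                 # 1 x filters
    } else {
      idx <- matrix(seq_len(n), nrow = 1L)
      fwd <- ad_lstm_seq(tape, C, idx, p$cf_Wx, p$cf_Wh, p$cf_b, reverse = FALSE)
      bwd <- ad_lstm_seq(tape, C, idx, p$cr_Wx, p$cr_Wh, p$cr_b, reverse = TRUE)
      per_tok[[k]] <- ad_hcat(tape, ad_rows(tape, fwd, n + 1L), ad_rows(tape, bwd, n + 1L))
    }
  }
  uniq_mat <- ad_vcat(tape, per_tok)
  ad_rows(tape, uniq_mat, match(tokens, uniq))
}

#' Embed the tokens of a document
#'
#' Word-table lookup (out-of-vocabulary tokens map to the unknown vector)
#' plus the optional character-level feature, concatenated per token.
#'
#' @param model a `seqc_model`.
#' @param tokens character vector.
#' @return numeric matrix, one row per token.
#' @export
embed_tokens <- function(model, tokens) {
  tape <- ad_tape()
  p <- wrap_params(tape, model)
  embed_tokens_graph(tape, p, model, tokens)$value
}

embed_tokens_graph <- function(tape, p, model, tokens) {
  if (length(tokens) == 0L) seqc_abort("value", "no tokens to embed")
  E <- ad_rows(tape, p$emb, token_ids(tokens, model$token_vocab))
  if (model$encoder_cfg$char_mode != "none")
    E <- ad_hcat(tape, E, char_features(tape, p, model, tokens))
  E
}

run_bilstm <- function(tape, X, idx, p, prefix) {
  N <- nrow(X$value); B <- nrow(idx)
  fwd <- ad_lstm_seq(tape, X, idx, p[[paste0(prefix, "f_Wx")]],
                     p[[paste0(prefix, "f_Wh")]], p[[paste0(prefix, "f_b")]],
                     reverse = FALSE)
  bwd <- ad_lstm_seq(tape, X, idx, p[[paste0(prefix, "r_Wx")]],
                     p[[paste0(prefix, "r_Wh")]], p[[paste0(prefix, "r_b")]],
                     reverse = TRUE)
  list(states = ad_hcat(tape, ad_rows(tape, fwd, seq_len(N)),
                        ad_rows(tape, bwd, seq_len(N))),
       finals = ad_hcat(tape, ad_rows(tape, fwd, N + seq_len(B)),
                        ad_rows(tape, bwd, N + seq_len(B))))
}

#' Encode a document with the hierarchical encoder
#'
#' @param model a `seqc_model`.
#' @param doc a `seqc_document`.
#' @param tape optionally, an existing autodiff tape (used by the training
#'   loop); by default a fresh one is created and the result is only used
#'   for its values.
#' @param params parameter nodes from `wrap_params` (internal use).
#' @param training apply dropout.
#' @return object of class `seqc_encoded`: nodes `word_states` (N x tau),
#'   `unit_vectors` (B x tau), `doc_vector` (1 x tau), plus `tokens` (flat
#'   token vector after truncation), `unit_of_word` (unit index per token)
#'   and `n_units`.
#' @export
encode_document <- function(model, doc, tape = NULL, params = NULL,
                            training = FALSE) {
  ec <- model$encoder_cfg
  units <- doc_units(doc, ec$level1_unit, ec$max_unit_tokens, ec$max_units)
  if (length(units) == 0L)
    seqc_abort("value", "document '%s' has no content to encode", doc$doc_id)
  if (is.null(tape)) tape <- ad_tape()
  if (is.null(params)) params <- wrap_params(tape, model)

  lens <- vapply(units, length, 1L)
  flat <- unlist(units)
  B <- length(units); N <- length(flat)
  idx <- matrix(0L, B, max(lens))
  at <- 0L
  for (b in seq_len(B)) {
    idx[b, seq_len(lens[b])] <- at + seq_len(lens[b])
    at <- at + lens[b]
  }

  E <- embed_tokens_graph(tape, params, model, flat)
  E <- ad_dropout(tape, E, ec$dropout, training)
  lvl1 <- run_bilstm(tape, E, idx, params, "s")
  lvl2 <- run_bilstm(tape, lvl1$finals, matrix(seq_len(B), nrow = 1L), params, "d")

  structure(list(
    tape = tape, params = params,
    word_states = lvl1$states,
    unit_vectors = lvl1$finals,
    doc_vector = ad_rows(tape, lvl2$finals, 1L),
    tokens = flat,
    unit_of_word = rep(seq_len(B), lens),
    n_units = B,
    doc_id = doc$doc_id
  ), class = "seqc_encoded")
}
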