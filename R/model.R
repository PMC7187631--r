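# Model object: configurations, token vocabulary, parameter initialisation
# and checkpointing for the hierarchical encoder + attentive decoder.

#' Encoder configuration
#'
#' Defaults follow the reference setup: 200-D word vectors, 25-D character
#' vectors (character features off by default; CNN of width 3 pooled to
#' 100-D, or a character Bi-LSTM with 50-D hidden halves), 100 hidden units
#' per LSTM direction at both levels (so every contextual vector has
#' dimension tau = 200), sentence caps of 128 tokens, section caps of 512,
#' at most 600 level-1 units, dropout 0.5.
#'
#' @param word_dim word-embedding size.
#' @param char_dim character-embedding size.
#' @param char_mode `"none"`, `"cnn"` or `"bilstm"`.
#' @param unit_hidden hidden units per direction of the sentence/section
#'   LSTM; tau = `2 * unit_hidden`.
#' @param doc_hidden hidden units per direction of the document LSTM; must
#'   equal `unit_hidden` so the document vector can seed the decoder.
#' @param level1_unit `"sentence"` (abstracts) or `"section"` (full texts,
#'   discourse mode).
#' @param max_unit_tokens per-unit token cap; default 128 for sentences,
#'   512 for sections.
#' @param max_units cap on level-1 units per document.
#' @param dropout dropout probability applied to embeddings and the
#'   decoder input during training.
#' @param char_cnn_filters,char_lstm_hidden sizes of the optional character
#'   encoders.
#' @param seed parameter-initialisation seed.
#' @return list of class `seqc_encoder_config`.
#' @export
encoder_config <- function(word_dim = 200L, char_dim = 25L,
                           char_mode = c("none", "cnn", "bilstm"),
                           unit_hidden = 100L, doc_hidden = unit_hidden,
                           level1_unit = c("sentence", "section"),
                           max_unit_tokens = NULL, max_units = 600L,
                           dropout = 0.5, char_cnn_filters = 100L,
                           char_lstm_hidden = 50L, seed = 1L) {
  char_mode <- match.arg(char_mode)
  level1_unit <- match.arg(level1_unit)
  if (doc_hidden != unit_hidden)
    seqc_abort("config", "doc_hidden must equal unit_hidden (shared tau)")
  if (word_dim < 1 || char_dim < 1 || unit_hidden < 1)
    seqc_abort("config", "dimensions must be positive")
  if (is.null(max_unit_tokens))
    max_unit_tokens <- if (level1_unit == "sentence") 128L else 512L
  structure(list(
    word_dim = as.integer(word_dim), char_dim = as.integer(char_dim),
    char_mode = char_mode, unit_hidden = as.integer(unit_hidden),
    doc_hidden = as.integer(doc_hidden), level1_unit = level1_unit,
    max_unit_tokens = as.integer(max_unit_tokens),
    max_units = as.integer(max_units), dropout = dropout,
    char_cnn_filters = as.integer(char_cnn_filters),
    char_lstm_hidden = as.integer(char_lstm_hidden),
    tau = 2L * as.integer(unit_hidden), seed = as.integer(seed)
  ), class = "seqc_encoder_config")
}

#' Decoder configuration
#'
#' @param mode attention mode: `"HAD"` (hierarchical attentive decoding,
#'   the full model), `"no_s_att"` (drop the sentence-level weighting),
#'   `"no_w_att"` (attend to unit vectors only) or `"no_attention"`
#'   (zero context; the decoder sees only the document vector).
#' @param beam_width default beam width for inference.
#' @return list of class `seqc_decoder_config`. The decoder hidden size and
#'   species-embedding size both equal the encoder's tau.
#' @export
decoder_config <- function(mode = c("HAD", "no_s_att", "no_w_att", "no_attention"),
                           beam_width = 5L) {
  mode <- match.arg(mode)
  if (beam_width < 1) seqc_abort("config", "beam_width must be >= 1")
  structure(list(mode = mode, beam_width = as.integer(beam_width)),
            class = "seqc_decoder_config")
}

#' Build a token vocabulary from a corpus
#'
#' Index 1 is the unknown-token slot. The mask symbol is always included.
#'
#' @param docs list of `seqc_document`.
#' @param min_count drop tokens rarer than this.
#' @return character vector; `attr(, "unk")` gives the unknown index (1).
#' @export
build_token_vocab <- function(docs, min_count = 1L) {
  counts <- table(unlist(lapply(docs, doc_tokens)))
  toks <- names(counts)[counts >= min_count]
  out <- c("<UNK>", SPECIES_MASK, sort(setdiff(toks, SPECIES_MASK)))
  attr(out, "unk") <- 1L
  out
}

token_ids <- function(tokens, vocab) {
  idx <- match(tokens, vocab)
  idx[is.na(idx)] <- 1L
  idx
}

glorot <- function(nr, nc, gain = 1) {
  r <- gain * sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

# LSTM cell parameters. Gain-2 uniform weights and a forget-gate bias of 1
# keep early activations from vanishing through the stacked recurrences;
# gate order is [input, forget, candidate, output].
lstm_params <- function(d_in, h, prefix) {
  b <- matrix(0, 1L, 4L * h)
  b[1L, h + seq_len(h)] <- 1
  out <- list(glorot(d_in, 4L * h, gain = 2), glorot(h, 4L * h, gain = 2), b)
  names(out) <- paste0(prefix, c("Wx", "Wh", "b"))
  out
}

#' Initialise a model
#'
#' Builds the full trainable parameter set for the hierarchical encoder and
#' the attentive label-sequence decoder. Weights use Glorot-uniform
#' initialisation, biases start at zero, embeddings uniform in ±0.1; all
#' randomness comes from `encoder_cfg$seed`.
#'
#' @param token_vocab from [build_token_vocab()].
#' @param label_vocab from [build_label_vocab()].
#' @param encoder_cfg an [encoder_config()].
#' @param decoder_cfg a [decoder_config()].
#' @param pretrained optional numeric matrix (`length(token_vocab)` x
#'   `word_dim`) of frozen word vectors, e.g. from [read_word_vectors()];
#'   when supplied the word table is not updated during training.
#' @return object of class `seqc_model`.
#' @export
init_model <- function(token_vocab, label_vocab, encoder_cfg = encoder_config(),
                       decoder_cfg = decoder_config(), pretrained = NULL) {
  ec <- encoder_cfg
  tau <- ec$tau
  m <- label_vocab$size
  d_in <- ec$word_dim +
    if (ec$char_mode == "cnn") ec$char_cnn_filters
    else if (ec$char_mode == "bilstm") 2L * ec$char_lstm_hidden else 0L

  params <- with_seed(ec$seed, {
    p <- list()
    if (is.null(pretrained))
      p$emb <- matrix(stats::runif(length(token_vocab) * ec$word_dim, -0.5, 0.5),
                      length(token_vocab), ec$word_dim)
    if (ec$char_mode != "none") {
      chars <- sort(unique(unlist(strsplit(token_vocab, ""))))
      p$char_emb <- matrix(stats::runif((length(chars) + 1L) * ec$char_dim, -0.1, 0.1),
                           length(chars) + 1L, ec$char_dim)
      if (ec$char_mode == "cnn") {
        p$char_Wc <- glorot(3L * ec$char_dim, ec$char_cnn_filters)
        p$char_bc <- matrix(0, 1L, ec$char_cnn_filters)
      } else {
        p <- c(p, lstm_params(ec$char_dim, ec$char_lstm_hidden, "cf_"),
               lstm_params(ec$char_dim, ec$char_lstm_hidden, "cr_"))
      }
      attr(p$char_emb, "chars") <- chars
    }
    p <- c(p,
      lstm_params(d_in, ec$unit_hidden, "sf_"),
      lstm_params(d_in, ec$unit_hidden, "sr_"),
      lstm_params(tau, ec$doc_hidden, "df_"),
      lstm_params(tau, ec$doc_hidden, "dr_"))
    p$spec_emb <- matrix(stats::runif((m + 2L) * tau, -0.1, 0.1), m + 2L, tau)
    p$att_W1 <- glorot(tau, tau)
    p$att_W2 <- glorot(tau, tau)
    p$att_v <- glorot(tau, 1L)
    p$att_b <- matrix(0, 1L, tau)
    p <- c(p, lstm_params(2L * tau, tau, "dec_"))
    p$out_W <- glorot(tau, m + 1L)
    p$out_b <- matrix(0, 1L, m + 1L)
    p[!vapply(p, is.null, TRUE)]
  })

  structure(list(
    encoder_cfg = ec, decoder_cfg = decoder_cfg,
    token_vocab = token_vocab, label_vocab = label_vocab,
    params = params,
    fixed = if (is.null(pretrained)) list() else {
      stopifnot(nrow(pretrained) == length(token_vocab), ncol(pretrained) == ec$word_dim)
      list(emb = pretrained)
    }
  ), class = "seqc_model")
}

#' @export
print.seqc_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<seqc_model: m=%d labels, |V|=%d tokens, tau=%d, mode=%s, %s trainable values>\n",
              x$label_vocab$size, length(x$token_vocab), x$encoder_cfg$tau,
              x$decoder_cfg$mode, format(np, big.mark = ",")))
  invisible(x)
}

# spec_emb row indices: 1..m labels, m+1 = EOS, m+2 = BOS (the trainable
# first-step input). Output alphabet indices: 1..m labels, m+1 = EOS.
spec_rows <- function(model) {
  m <- model$label_vocab$size
  list(eos = m + 1L, bos = m + 2L)
}

#' Read word vectors in word2vec/GloVe text format
#'
#' Plain text, one token per line followed by its numbers; an optional
#' `count dim` header line is detected and skipped. Tokens absent from the
#' file get the zero vector.
#'
#' @param path text file of vectors.
#' @param token_vocab tokens to extract.
#' @param word_dim expected dimensionality.
#' @return numeric matrix `length(token_vocab)` x `word_dim`.
#' @export
read_word_vectors <- function(path, token_vocab, word_dim) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) > 0L) {
    first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
    if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first))))
      lines <- lines[-1]  # word2vec header
  }
  out <- matrix(0, length(token_vocab), word_dim)
  want <- stats::setNames(seq_along(token_vocab), token_vocab)
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) != word_dim + 1L) next
    row <- want[parts[1]]
    if (!is.na(row)) out[row, ] <- as.numeric(parts[-1])
  }
  out
}

#' Save a model checkpoint
#'
#' One archive holding configurations, vocabularies and parameters.
#'
#' @param model a `seqc_model`.
#' @param path output file (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return a `seqc_model`.
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "seqc_model")) seqc_abort("config", "not a seqc_model checkpoint")
  m
}
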