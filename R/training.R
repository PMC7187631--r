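# Teacher-forced training of the encoder-decoder with Adam.
#
# The per-document objective is the mean step cross-entropy of the gold
# virtual label sequence (labels in vocabulary order, EOS-terminated); the
# previous label fed at each step is the gold one, and the no-repeat mask
# is built from the gold prefix. Batches average the per-document losses;
# the constant factor relative to a plain sum is absorbed by the learning
# rate.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param epochs maximum epochs (default 100).
#' @param batch_size documents per optimizer step. The default 1 (plain
#'   stochastic updates) converges fastest for the small corpora this
#'   implementation targets; larger batches trade steps for smoother
#'   gradients.
#' @param dropout dropout probability during training (default 0.5);
#'   overrides the encoder configuration while fitting.
#' @param patience early-stopping patience, in epochs without a dev
#'   micro-F1 improvement (default 10).
#' @param seed shuffling/dropout seed.
#' @param verbose print one line per epoch.
#' @return list of class `seqc_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 100L, batch_size = 1L,
                         dropout = 0.5, patience = 10L, seed = 1L,
                         verbose = FALSE) {
  if (learning_rate <= 0) seqc_abort("config", "learning_rate must be positive")
  if (epochs < 1) seqc_abort("config", "epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), dropout = dropout,
                 patience = as.integer(patience), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "seqc_train_config")
}

# Gold decoding targets for a label set: output-alphabet indices
# (1..m labels in vocabulary order, then m+1 = EOS) and the spec_emb row
# fed as the "previous label" at each step (BOS first).
gold_targets <- function(model, labels) {
  vocab <- model$label_vocab
  idx <- sort(label_index(vocab, unique(as.character(labels))))
  m <- vocab$size
  targets <- c(idx, m + 1L)
  prev_rows <- c(spec_rows(model)$bos, idx)
  list(targets = targets, prev_rows = prev_rows)
}

# Build the teacher-forced loss graph for one document; returns the scalar
# loss node (value in $value) on enc$tape.
teacher_forced_loss_graph <- function(model, enc, labels, training = FALSE) {
  tape <- enc$tape
  p <- enc$params
  g <- gold_targets(model, labels)
  m <- model$label_vocab$size
  h <- enc$doc_vector
  tau <- ncol(h$value)
  cell <- ad_leaf(tape, matrix(0, 1L, tau))
  ctx <- ad_leaf(tape, matrix(0, 1L, tau))
  steps <- length(g$targets)
  total <- NULL
  for (t in seq_len(steps)) {
    att <- attend_graph(tape, p, enc, h, model$decoder_cfg$mode)
    x <- ad_hcat(tape, ad_rows(tape, p$spec_emb, g$prev_rows[t]), ctx)
    x <- ad_dropout(tape, x, model$encoder_cfg$dropout, training)
    out <- dec_cell(tape, p, x, h, cell)
    h <- out$h; cell <- out$cell; ctx <- att$ctx
    logits <- ad_add(tape, ad_matmul(tape, out$h, p$out_W), p$out_b)
    mask <- repeat_mask(m, g$targets[seq_len(t - 1L)][g$targets[seq_len(t - 1L)] <= m])
    lt <- ad_masked_ce(tape, logits, g$targets[t], mask)
    total <- if (is.null(total)) lt else ad_add(tape, total, lt)
  }
  ad_scale(tape, total, 1 / steps)
}

#' Teacher-forced cross-entropy loss of one document
#'
#' Mean over decoding steps of the negative log-probability of the gold
#' symbol, with gold previous labels fed to the decoder and the no-repeat
#' mask built from the gold prefix.
#'
#' @param model a `seqc_model`.
#' @param doc a labeled `seqc_document` (or pass `labels`).
#' @param labels gold label set; defaults to `doc$labels`.
#' @return non-negative scalar.
#' @export
teacher_forced_loss <- function(model, doc, labels = doc$labels) {
  if (is.null(labels)) seqc_abort("value", "document '%s' has no labels", doc$doc_id)
  enc <- encode_document(model, doc)
  teacher_forced_loss_graph(model, enc, labels)$value[1L, 1L]
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# Accumulate one document's parameter gradients into `acc` (named list).
doc_gradients <- function(model, doc, training = TRUE) {
  tape <- ad_tape()
  params <- wrap_params(tape, model)
  enc <- encode_document(model, doc, tape = tape, params = params,
                         training = training)
  loss <- teacher_forced_loss_graph(model, enc, doc$labels, training = training)
  ad_backward(tape, loss)
  grads <- lapply(names(model$params), function(nm)
    params[[nm]]$grad %||% (model$params[[nm]] * 0))
  names(grads) <- names(model$params)
  list(loss = loss$value[1L, 1L], grads = grads)
}

#' Train the encoder-decoder
#'
#' Teacher-forced cross-entropy minimised with Adam, early stopping on dev
#' micro-F1 (greedy decoding each epoch); the checkpoint with the best dev
#' micro-F1 is returned. Fully reproducible for a given seed on one
#' platform.
#'
#' @param train_docs,dev_docs labeled `seqc_document` lists.
#' @param encoder_cfg an [encoder_config()].
#' @param decoder_cfg a [decoder_config()].
#' @param train_cfg a [train_config()].
#' @param all_labels optional label universe for the vocabulary (defaults
#'   to the labels observed in training).
#' @param pretrained optional frozen word-vector matrix (see
#'   [init_model()]); its rows must follow the token vocabulary built here.
#' @return list: `model` (best checkpoint), `log` (one row per epoch:
#'   epoch, train_loss, dev_hamming, dev_micro_f1, dev_macro_f1),
#'   `best_epoch`.
#' @export
fit_seqc <- function(train_docs, dev_docs, encoder_cfg = encoder_config(),
                     decoder_cfg = decoder_config(),
                     train_cfg = train_config(), all_labels = NULL,
                     pretrained = NULL) {
  if (length(train_docs) == 0L) seqc_abort("config", "empty training corpus")
  has_labels <- vapply(train_docs, function(d) !is.null(d$labels), TRUE)
  if (!all(has_labels))
    seqc_abort("config", "all training documents must be labeled")
  label_vocab <- build_label_vocab(lapply(train_docs, `[[`, "labels"), all_labels)
  token_vocab <- build_token_vocab(train_docs)
  encoder_cfg$dropout <- train_cfg$dropout
  model <- init_model(token_vocab, label_vocab, encoder_cfg, decoder_cfg,
                      pretrained = pretrained)
  dev_gold <- lapply(dev_docs, `[[`, "labels")
  names(dev_gold) <- vapply(dev_docs, `[[`, character(1), "doc_id")

  opt <- adam_state(model$params)
  best <- list(f1 = -Inf, params = model$params, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    dev_hamming = numeric(), dev_micro_f1 = numeric(),
                    dev_macro_f1 = numeric())

  with_seed(train_cfg$seed, {
    n <- length(train_docs)
    stale <- 0L
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = train_cfg$batch_size)) {
        batch <- ord[start:min(start + train_cfg$batch_size - 1L, n)]
        acc <- lapply(model$params, function(p) p * 0)
        for (di in batch) {
          dg <- doc_gradients(model, train_docs[[di]], training = TRUE)
          epoch_loss <- epoch_loss + dg$loss
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + dg$grads[[nm]]
        }
        acc <- lapply(acc, function(g) g / length(batch))
        upd <- adam_update(model$params, acc, opt, train_cfg$learning_rate)
        model$params <- upd$params
        opt <- upd$state
      }
      dev_row <- c(dev_hamming = NA_real_, dev_micro_f1 = NA_real_,
                   dev_macro_f1 = NA_real_)
      if (length(dev_docs) > 0L) {
        preds <- predict_corpus(model, dev_docs, beam = 1L)
        rep_ <- evaluate_predictions(preds, dev_gold, label_vocab)
        dev_row <- c(dev_hamming = rep_$hamming,
                     dev_micro_f1 = unname(rep_$micro["f1"]),
                     dev_macro_f1 = rep_$macro_f1)
        if (dev_row[["dev_micro_f1"]] > best$f1 + 1e-12) {
          best <- list(f1 = dev_row[["dev_micro_f1"]], params = model$params,
                       epoch = epoch)
          stale <- 0L
        } else stale <- stale + 1L
      }
      log <- rbind(log, data.frame(epoch = epoch, train_loss = epoch_loss / n,
                                   dev_hamming = dev_row[["dev_hamming"]],
                                   dev_micro_f1 = dev_row[["dev_micro_f1"]],
                                   dev_macro_f1 = dev_row[["dev_macro_f1"]]))
      if (train_cfg$verbose)
        message(sprintf("epoch %3d  loss %.4f  dev micro-F1 %s", epoch,
                        epoch_loss / n,
                        format(dev_row[["dev_micro_f1"]], digits = 4)))
      if (length(dev_docs) > 0L &&
          (best$f1 >= 1 - 1e-12 || stale >= train_cfg$patience)) break
    }
  })
  if (length(dev_docs) > 0L) model$params <- best$params
  list(model = model, log = log,
       best_epoch = if (length(dev_docs) > 0L) best$epoch else nrow(log))
}
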