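# Decoding behaviour: masking, greedy/beam equivalence against the
# brute-force oracles defined in helper-oracles.R, and attention export.

test_that("attention weights normalize and single-token documents are forced", {
  model <- tiny_model(m = 3, seed = 5)
  doc <- make_doc("one", list("tok7"))
  res <- greedy_decode(model, doc)
  for (st in res$attention) {
    expect_equal(sum(st$alpha), 1, tolerance = 1e-6)
    expect_equal(sum(st$beta), 1, tolerance = 1e-6)
    expect_equal(st$alpha, 1)
  }
})

test_that("zero attention parameters give uniform attention and the mean context", {
  model <- tiny_model(m = 2, seed = 5)
  for (nm in c("att_W1", "att_W2", "att_v", "att_b"))
    model$params[[nm]] <- model$params[[nm]] * 0
  doc <- tiny_random_doc(31, n_sent = 2)
  enc <- encode_document(model, doc)
  st <- decoder_step(model, enc)
  n <- length(enc$tokens)
  expect_equal(st$alpha, rep(1 / n, n), tolerance = 1e-12)
  expect_equal(st$beta, rep(1 / 2, 2), tolerance = 1e-12)
})

test_that("zero output layer with nothing masked gives a uniform distribution", {
  model <- tiny_model(m = 3, seed = 8)
  model$params$out_W <- model$params$out_W * 0
  model$params$out_b <- model$params$out_b * 0
  enc <- encode_document(model, tiny_random_doc(17))
  st <- decoder_step(model, enc)
  expect_equal(unname(st$dist), rep(1 / 4, 4), tolerance = 1e-12)
})

test_that("predicted labels are masked to exact zero at all later steps", {
  model <- tiny_model(m = 3, seed = 9)
  enc <- encode_document(model, tiny_random_doc(23))
  st1 <- decoder_step(model, enc)
  k1 <- which.max(st1$dist[1:3])  # force a label, not EOS
  state <- seqspecies:::state_emit(st1$state, k1, 3)
  st2 <- decoder_step(model, enc, state, k1)
  expect_identical(unname(st2$dist[[k1]]), 0)
  expect_equal(sum(st2$dist), 1, tolerance = 1e-12)
  # with m-1 labels predicted, support is the last label and EOS only
  k2 <- setdiff(1:3, k1)[1]
  state2 <- seqspecies:::state_emit(st2$state, k2, 3)
  st3 <- decoder_step(model, enc, state2, k2)
  expect_identical(unname(st3$dist[[k1]]), 0)
  expect_identical(unname(st3$dist[[k2]]), 0)
  expect_setequal(names(st3$dist)[st3$dist > 0],
                  c(model$label_vocab$labels[setdiff(1:3, c(k1, k2))], EOS))
  # stepping after EOS is an error
  state3 <- seqspecies:::state_emit(st3$state, 4L, 3)
  expect_error(decoder_step(model, enc, state3, NULL),
               class = "seqspecies_state_error")
})

test_that("greedy decoding never repeats labels and stops by m+1 steps", {
  for (seed in 1:10) {
    model <- tiny_model(m = 4, seed = seed)
    res <- greedy_decode(model, tiny_random_doc(seed + 40))
    expect_equal(anyDuplicated(res$labels), 0)
    expect_lte(length(res$labels), 4)
    expect_equal(res$sequence[1], BOS)
    expect_equal(res$sequence[length(res$sequence)], EOS)
  }
})

test_that("greedy equals beam search with width 1", {
  for (seed in 1:25) {
    model <- tiny_model(m = 3, seed = seed)
    doc <- tiny_random_doc(seed)
    enc <- encode_document(model, doc)
    g <- greedy_decode(model, enc)
    b <- beam_search(model, enc, width = 1)
    expect_identical(g$sequence, b$sequence)
    expect_equal(g$log_prob, b$log_prob, tolerance = 1e-10)
  }
})

test_that("exhaustive beam search matches brute-force enumeration", {
  set.seed(77)
  for (trial in 1:18) {
    m <- sample(2:4, 1)
    model <- tiny_model(m = m, seed = 1000 + trial)
    doc <- tiny_random_doc(2000 + trial)
    enc <- encode_document(model, doc)
    b <- beam_search(model, enc, width = 200)
    oracle <- enumerate_best(model, enc)
    got <- seqspecies:::label_index(model$label_vocab, b$labels)
    expect_equal(unname(got), unname(oracle$seq), label = sprintf("trial %d", trial))
    expect_equal(b$log_prob, oracle$lp, tolerance = 1e-9)
  }
})

test_that("beam log-probability equals an independent recomputation of its own steps", {
  for (seed in 1:8) {
    model <- tiny_model(m = 3, seed = seed + 300)
    doc <- tiny_random_doc(seed + 500)
    enc <- encode_document(model, doc)
    b <- beam_search(model, enc, width = 5)
    idx <- if (length(b$labels)) seqspecies:::label_index(model$label_vocab, b$labels)
           else integer()
    expect_equal(score_seq(model, enc, idx), b$log_prob, tolerance = 1e-9)
    # when the emitted order is the canonical vocabulary order, the
    # teacher-forced loss of the same label set scores the same path
    if (!is.unsorted(idx)) {
      loss <- teacher_forced_loss(model, doc, labels = b$labels)
      expect_equal(-loss * (length(idx) + 1L), b$log_prob, tolerance = 1e-9)
    }
  }
})

test_that("ablation modes decode with valid attention maps", {
  doc <- tiny_random_doc(61, n_sent = 3)
  for (mode in c("HAD", "no_s_att", "no_w_att", "no_attention")) {
    model <- tiny_model(m = 3, seed = 44, mode = mode)
    model$decoder_cfg <- decoder_config(mode = mode)
    res <- greedy_decode(model, doc)
    for (st in res$attention) {
      expect_equal(sum(st$alpha), 1, tolerance = 1e-6)
      expect_equal(sum(st$beta), 1, tolerance = 1e-6)
      expect_true(all(st$alpha >= 0) && all(st$beta >= 0))
    }
  }
})

test_that("attention export aligns weights with the document tokens", {
  model <- tiny_model(m = 3, seed = 12)
  doc <- tiny_random_doc(71, n_sent = 2)
  res <- greedy_decode(model, doc)
  rep_ <- export_attention(res, doc, model)
  expect_equal(rep_$tokens, doc_tokens(doc))
  expect_length(rep_$steps, length(res$labels) + 1L)  # labels + EOS
  for (st in rep_$steps) {
    expect_length(st$token_weights, length(rep_$tokens))
    expect_equal(sum(st$token_weights), 1, tolerance = 1e-6)
  }
  expect_equal(rep_$steps[[length(rep_$steps)]]$label, EOS)
  other <- tiny_random_doc(72, n_sent = 2)
  expect_error(export_attention(res, other, model),
               class = "seqspecies_alignment_error")
})
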