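test_that("encoding produces tau-dimensional states with matching counts", {
  model <- tiny_model(m = 2, seed = 2)
  doc <- tiny_random_doc(5, n_sent = 3)
  enc <- encode_document(model, doc)
  tau <- model$encoder_cfg$tau
  n_tokens <- length(doc_tokens(doc))
  expect_equal(dim(enc$word_states$value), c(n_tokens, tau))
  expect_equal(dim(enc$unit_vectors$value), c(3, tau))
  expect_equal(dim(enc$doc_vector$value), c(1, tau))
  expect_true(all(is.finite(enc$word_states$value)))
  expect_equal(length(enc$unit_of_word), n_tokens)
})

test_that("truncation caps unit length and unit count", {
  model <- tiny_model(m = 2, seed = 2)
  model$encoder_cfg$max_unit_tokens <- 4L
  model$encoder_cfg$max_units <- 2L
  doc <- make_doc("long", list(paste(rep("tok1", 10), collapse = " "),
                               "tok2 tok3", "tok4 tok5 tok6"))
  enc <- encode_document(model, doc)
  expect_equal(enc$n_units, 2)
  expect_equal(length(enc$tokens), 4 + 2)
  expect_equal(dim(enc$word_states$value)[1], 6)
})

test_that("zero parameters give zero encodings; empty documents error", {
  model <- tiny_model(m = 2, seed = 3)
  model$params <- lapply(model$params, function(p) p * 0)
  enc <- encode_document(model, tiny_random_doc(9, n_sent = 2))
  expect_true(all(enc$word_states$value == 0))
  expect_true(all(enc$doc_vector$value == 0))
  expect_error(encode_document(model, seqc_document("empty")),
               class = "seqspecies_value_error")
})

test_that("shared unit parameters: the same sentence encodes identically anywhere", {
  model <- tiny_model(m = 2, seed = 7)
  doc <- make_doc("rep", list("tok1 tok2 tok3", "tok9 tok8", "tok1 tok2 tok3"))
  enc <- encode_document(model, doc)
  uw <- enc$unit_of_word
  expect_equal(enc$word_states$value[uw == 1, ],
               enc$word_states$value[uw == 3, ], tolerance = 1e-12)
  expect_equal(enc$unit_vectors$value[1, ], enc$unit_vectors$value[3, ],
               tolerance = 1e-12)
})

test_that("encoding is permutation-sensitive at the unit level", {
  model <- tiny_model(m = 2, seed = 7)
  d1 <- make_doc("o1", list("tok1 tok2", "tok3 tok4"))
  d2 <- make_doc("o2", list("tok3 tok4", "tok1 tok2"))
  e1 <- encode_document(model, d1)
  e2 <- encode_document(model, d2)
  expect_gt(max(abs(e1$doc_vector$value - e2$doc_vector$value)), 1e-8)
})

test_that("token embedding is deterministic with an unknown-token fallback", {
  model <- tiny_model(m = 2, seed = 1)
  E <- embed_tokens(model, c("tok1", "tok1", "neverseen"))
  expect_equal(E[1, ], E[2, ])
  expect_equal(E[3, ], model$params$emb[1, ])  # row 1 is <UNK>
})

test_that("character CNN features have the configured width and dimension", {
  labels <- c("LabelA", "LabelB")
  lv <- build_label_vocab(list(labels), all_labels = labels)
  tv <- build_token_vocab(list(make_doc("s", list("ab abc xyz"))))
  ec <- encoder_config(word_dim = 4, char_mode = "cnn", char_dim = 3,
                       char_cnn_filters = 6, unit_hidden = 2, dropout = 0,
                       seed = 5)
  model <- init_model(tv, lv, ec, decoder_config())
  E <- embed_tokens(model, c("ab", "a"))
  expect_equal(ncol(E), 4 + 6)
  # single-character token: pooling over one window
  chars <- attr(model$params$char_emb, "chars")
  ce <- model$params$char_emb[match("a", chars) + 1L, ]
  win <- c(rep(0, 3), ce, rep(0, 3))
  ref <- tanh(win %*% model$params$char_Wc + model$params$char_bc)
  expect_equal(E[2, 5:10], as.vector(ref), tolerance = 1e-12)

  # char bilstm variant runs and has the right width
  ec2 <- encoder_config(word_dim = 4, char_mode = "bilstm", char_dim = 3,
                        char_lstm_hidden = 2, unit_hidden = 2, dropout = 0,
                        seed = 5)
  m2 <- init_model(tv, lv, ec2, decoder_config())
  expect_equal(ncol(embed_tokens(m2, "abc")), 4 + 4)
})

test_that("frozen pretrained embeddings survive a training step, trainable ones move", {
  labels <- "LabelA"
  docs <- lapply(1:4, function(i) {
    d <- tiny_random_doc(100 + i, n_sent = 2); d$labels <- labels; d
  })
  tv <- build_token_vocab(docs)
  lv <- build_label_vocab(list(labels), all_labels = labels)
  ec <- encoder_config(word_dim = 3, unit_hidden = 2, dropout = 0, seed = 2)
  pre <- matrix(rnorm(length(tv) * 3), length(tv), 3)

  frozen <- init_model(tv, lv, ec, decoder_config(), pretrained = pre)
  fit1 <- within_one_step(frozen, docs)
  expect_identical(fit1$fixed$emb, pre)
  expect_false("emb" %in% names(fit1$params))

  trainable <- init_model(tv, lv, ec, decoder_config())
  before <- trainable$params$emb
  fit2 <- within_one_step(trainable, docs)
  expect_gt(max(abs(fit2$params$emb - before)), 0)
})
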