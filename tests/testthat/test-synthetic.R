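test_that("generation is deterministic per seed and respects the config", {
  sp <- c("Mouse", "Rat", "Frog")
  cfg <- synthetic_config(num_docs = 30, species = sp, label_probs = 0.4,
                          p_mention = 0.5, cues_per_species = 2, seed = 9)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$docs, c2$docs)
  expect_identical(c1$manifest, c2$manifest)
  expect_length(c1$docs, 30)
  for (d in c1$docs) {
    expect_gte(length(d$labels), 1)
    expect_true(all(d$labels %in% sp))
    ns <- length(d$abstract)
    expect_true(ns >= cfg$sentences_per_doc[1])
  }
})

test_that("label frequencies follow the configured distribution", {
  cfg <- synthetic_config(num_docs = 2000, species = c("Mouse", "Rat"),
                          label_probs = c(Mouse = 0.5, Rat = 0.5),
                          p_mention = 0, cues_per_species = 1,
                          sentences_per_doc = 2:3, sentence_len = 3:5, seed = 31)
  corp <- generate_corpus(cfg)
  freq <- mean(vapply(corp$docs, function(d) "Mouse" %in% d$labels, TRUE))
  # inclusion probability 0.5 before the >=1-label rejection; the
  # conditional per-species rate is 0.5 / (1 - 0.25) = 2/3
  expect_lt(abs(freq - 2 / 3), 0.03)
})

test_that("with certain mentions the dictionary recovers gold exactly", {
  sp <- c("Cat", "Guinea pig", "Mouse", "Spiny lobster")
  cfg <- synthetic_config(num_docs = 150, species = sp, label_probs = 0.35,
                          p_mention = 1, cues_per_species = 1, seed = 17)
  corp <- generate_corpus(cfg)
  preds <- lapply(corp$docs, annotate_mention_labels, lex = the_lexicon)
  gold <- lapply(corp$docs, `[[`, "labels")
  expect_equal(micro_f1(preds, gold)[["f1"]], 1)
  expect_equal(hamming_loss(preds, gold, sp), 0)
})

test_that("every species in the subset occurs given enough documents", {
  sp <- c("Mouse", "Rat", "Frog", "Turtle")
  cfg <- synthetic_config(num_docs = 200, species = sp, label_probs = 0.3,
                          p_mention = 1, seed = 23)
  corp <- generate_corpus(cfg)
  expect_setequal(unique(unlist(lapply(corp$docs, `[[`, "labels"))), sp)
})

test_that("the manifest faithfully records every planted mention and cue", {
  sp <- c("Mouse", "Zebrafish")
  cfg <- synthetic_config(num_docs = 40, species = sp, label_probs = 0.5,
                          p_mention = 1, cues_per_species = 2, seed = 41)
  corp <- generate_corpus(cfg)
  for (d in corp$docs) {
    man <- corp$manifest[[d$doc_id]]
    expect_identical(man$labels, d$labels)
    for (mn in man$mentions) {
      toks <- d$abstract[[mn$sentence]][mn$position:(mn$position + mn$n_tokens - 1L)]
      expect_identical(tolower(paste(toks, collapse = " ")), mn$form)
    }
    for (cu in man$cues)
      expect_identical(d$abstract[[cu$sentence]][cu$position], cu$cue)
    # every gold species plants all of its cues
    cued <- unique(vapply(man$cues, `[[`, character(1), "species"))
    expect_setequal(cued, d$labels)
  }
})

test_that("the masked benchmark hides all mentions but keeps labels and cues", {
  sp <- c("Monkey", "Mouse", "Rat")
  cfg <- synthetic_config(num_docs = 60, species = sp, label_probs = 0.4,
                          p_mention = 1, cues_per_species = 2, seed = 53)
  bench <- make_masked_benchmark(cfg, ratios = c(0.6, 0.2, 0.2))
  all_docs <- c(bench$train, bench$dev, bench$test)
  expect_length(all_docs, 60)
  for (d in all_docs) {
    expect_true(d$masked)
    expect_equal(nrow(find_mentions(d, the_lexicon)), 0)
    expect_gte(length(d$labels), 1)
  }
  # a cue-lookup oracle scores perfectly on the test split
  cue_to_species <- stats::setNames(
    rep(names(bench$cues), lengths(bench$cues)), unlist(bench$cues))
  oracle <- lapply(bench$test, function(d)
    sort(unique(unname(cue_to_species[intersect(doc_tokens(d),
                                                names(cue_to_species))]))))
  gold <- lapply(bench$test, `[[`, "labels")
  expect_equal(micro_f1(oracle, gold)[["f1"]], 1)
  expect_error(make_masked_benchmark(
    synthetic_config(num_docs = 5, species = "Mouse", p_mention = 0)),
    class = "seqspecies_config_error")
})

test_that("discourse mode produces sectioned documents", {
  cfg <- synthetic_config(num_docs = 10, species = "Mouse", label_probs = 1,
                          p_mention = 1, n_sections = 3,
                          sentences_per_doc = 6:8, seed = 3)
  corp <- generate_corpus(cfg)
  for (d in corp$docs) {
    expect_gte(length(d$sections), 2)
    expect_length(d$abstract, 0)
  }
  # sectioned docs encode in section mode
  model <- tiny_model(m = 2, seed = 5)
  model$encoder_cfg$level1_unit <- "section"
  enc <- encode_document(model, corp$docs[[1]])
  expect_equal(enc$n_units, length(corp$docs[[1]]$sections))
})
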