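# Shared fixtures: tiny documents, tiny models, and cached corpora.

the_lexicon <- compile_default_lexicon()

make_doc <- function(id, sentences, labels = NULL, title = character(),
                     sections = list()) {
  seqc_document(id,
                title = title,
                abstract = lapply(sentences, tokenize_text),
                sections = sections,
                labels = labels)
}

# The masked-inference worked example: monkey cell lines grafted in mouse.
example_mask_doc <- function() {
  make_doc("ex1", c(
    paste("We have established monkey NPC cell lines from induced",
          "pluripotent stem cells iPSCs that can differentiate into",
          "GABAergic neurons in vitro"),
    "as well as in mouse brains without tumor formation"))
}

record_xml <- function(id = "12345", title = "A neural study",
                       abstract = "Neurons fire. Mice run.",
                       body = "", keywords = c("brain", "memory")) {
  paste0(
    '<record source="pubmed" id="', id, '">',
    if (nzchar(title)) paste0("<title>", title, "</title>") else "",
    if (nzchar(abstract)) paste0("<abstract>", abstract, "</abstract>") else "",
    paste0("<keyword>", keywords, "</keyword>", collapse = ""),
    "<date>2019-05-01</date>",
    body,
    "</record>")
}

# A tiny randomly initialised model over `m` labels; documents drawn from a
# small closed token set.
tiny_model <- function(m = 3L, seed = 1L, mode = "HAD", word_dim = 5L,
                       unit_hidden = 3L, dropout = 0) {
  labels <- paste0("Label", LETTERS[seq_len(m)])
  label_vocab <- build_label_vocab(lapply(seq_len(m), function(i) labels[i]),
                                   all_labels = labels)
  tokens <- c(paste0("tok", 1:20))
  token_vocab <- build_token_vocab(list(make_doc("seed", list(paste(tokens, collapse = " ")))))
  ec <- encoder_config(word_dim = word_dim, unit_hidden = unit_hidden,
                       dropout = dropout, seed = seed)
  init_model(token_vocab, label_vocab, ec, decoder_config())
}

tiny_random_doc <- function(seed, n_sent = NULL) {
  set.seed(seed)
  n_sent <- n_sent %||% sample(1:4, 1)
  make_doc(paste0("rnd", seed),
           lapply(seq_len(n_sent), function(i)
             paste(sample(paste0("tok", 1:20), sample(2:7, 1), replace = TRUE),
                   collapse = " ")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cached synthetic benchmark at the reference study conditions: 600 train /
# 100 dev / 100 test masked documents over 6 species, two cues per species,
# every mention planted then masked.
bench_env <- new.env()
acceptance_benchmark <- function() {
  if (is.null(bench_env$bench)) {
    cfg <- synthetic_config(
      num_docs = 800,
      species = c("Cat", "Human", "Monkey", "Mouse", "Rat", "Zebrafish"),
      label_probs = 0.3, p_mention = 1, cues_per_species = 2, seed = 101)
    bench_env$bench <- make_masked_benchmark(cfg)
    bench_env$species <- cfg$species
  }
  bench_env
}

# Apply a single Adam step over `docs` to a ready-made model.
within_one_step <- function(model, docs, lr = 0.001) {
  acc <- lapply(model$params, function(p) p * 0)
  for (d in docs) {
    dg <- seqspecies:::doc_gradients(model, d, training = FALSE)
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + dg$grads[[nm]]
  }
  acc <- lapply(acc, function(g) g / length(docs))
  upd <- seqspecies:::adam_update(model$params, acc,
                                  seqspecies:::adam_state(model$params), lr)
  model$params <- upd$params
  model
}

gold_sets_of <- function(docs)
  stats::setNames(lapply(docs, `[[`, "labels"),
                  vapply(docs, `[[`, character(1), "doc_id"))
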