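# Synthetic labeled corpora with controllable structure.
#
# Documents are built from filler sentences over an invented background
# vocabulary. Each gold species plants (a) an explicit lexicon surface form
# with probability p_mention — exercising the dictionary regime — and (b) a
# fixed number of species-specific cue tokens, invented words that collide
# with neither the lexicon nor the background vocabulary, so label
# information survives mention masking (the stand-in for genes/organs/
# functions signalling a species in real abstracts).

#' Synthetic corpus configuration
#'
#' @param num_docs number of documents.
#' @param species character vector of canonical labels (subset of the
#'   lexicon's canonicals).
#' @param label_probs per-species inclusion probability; single number or
#'   named vector over `species` (default 0.3). Every document is
#'   guaranteed at least one label.
#' @param p_mention probability that a gold species is explicitly named.
#' @param cues_per_species number of distinct cue tokens per species, all
#'   planted in every document carrying that species (default 2).
#' @param sentences_per_doc integer range (default 4:8).
#' @param sentence_len integer range of filler-sentence lengths (default
#'   5:15).
#' @param n_sections 0 for abstract-only documents; otherwise sentences
#'   are spread over this many titled sections (discourse mode).
#' @param background_vocab size of the filler vocabulary (default 200).
#' @param seed RNG seed.
#' @return list of class `seqc_synth_config`.
#' @export
synthetic_config <- function(num_docs, species, label_probs = 0.3,
                             p_mention = 1, cues_per_species = 2L,
                             sentences_per_doc = 4:8, sentence_len = 5:15,
                             n_sections = 0L, background_vocab = 200L,
                             seed = 1L) {
  if (num_docs < 1) seqc_abort("config", "num_docs must be >= 1")
  if (length(species) < 1) seqc_abort("config", "at least one species required")
  if (p_mention < 0 || p_mention > 1)
    seqc_abort("config", "p_mention must be in [0, 1]")
  if (length(label_probs) == 1L && is.null(names(label_probs)))
    label_probs <- stats::setNames(rep(label_probs, length(species)), species)
  if (!setequal(names(label_probs), species) ||
      any(label_probs < 0 | label_probs > 1))
    seqc_abort("config", "label_probs must be probabilities named by species")
  structure(list(
    num_docs = as.integer(num_docs), species = as.character(species),
    label_probs = label_probs[species], p_mention = p_mention,
    cues_per_species = as.integer(cues_per_species),
    sentences_per_doc = as.integer(sentences_per_doc),
    sentence_len = as.integer(sentence_len),
    n_sections = as.integer(n_sections),
    background_vocab = as.integer(background_vocab),
    seed = as.integer(seed)
  ), class = "seqc_synth_config")
}

cue_tokens_for <- function(species, k) {
  lapply(stats::setNames(species, species), function(s)
    paste0("cue", gsub("[^A-Za-z]", "", s), seq_len(k)))
}

#' Generate a synthetic labeled corpus
#'
#' @param cfg a [synthetic_config()].
#' @param lex lexicon supplying surface forms (default
#'   [compile_default_lexicon()]).
#' @return list of class `seqc_synth_corpus`: `docs` (labeled
#'   `seqc_document`s), `manifest` (per document: the planted mention and
#'   cue positions), `cues` (species -> cue tokens) and `cfg`.
#' @export
generate_corpus <- function(cfg, lex = compile_default_lexicon()) {
  unknown <- setdiff(cfg$species, lex$canonicals)
  if (length(unknown) > 0L)
    seqc_abort("config", "species '%s' not in the lexicon", unknown[1])
  cues <- cue_tokens_for(cfg$species, cfg$cues_per_species)
  background <- sprintf("bg%03d", seq_len(cfg$background_vocab))
  forms_of <- lapply(stats::setNames(cfg$species, cfg$species), function(s)
    lex$forms$form[lex$forms$canonical == s])

  with_seed(cfg$seed, {
    docs <- vector("list", cfg$num_docs)
    manifest <- vector("list", cfg$num_docs)
    for (d in seq_len(cfg$num_docs)) {
      repeat {
        gold <- cfg$species[stats::runif(length(cfg$species)) < cfg$label_probs]
        if (length(gold) > 0L) break
      }
      n_sent <- sample(cfg$sentences_per_doc, 1L)
      sents <- lapply(seq_len(n_sent), function(i)
        sample(background, sample(cfg$sentence_len, 1L), replace = TRUE))
      # Planted spans must not be split by later insertions, and their
      # recorded positions must reflect the final sentence; each sentence
      # keeps a list of half-open spans [start, end) with their payloads,
      # shifted as insertions land before them.
      planted <- rep(list(list()), n_sent)
      insert_at <- function(sent_i, toks, payload) {
        s <- sents[[sent_i]]
        cand <- seq_len(length(s) + 1L)
        for (iv in planted[[sent_i]])
          cand <- cand[cand <= iv$span[1] | cand >= iv$span[2]]
        pos <- cand[sample.int(length(cand), 1L)]
        sents[[sent_i]] <<- append(s, toks, after = pos - 1L)
        planted[[sent_i]] <<- c(
          lapply(planted[[sent_i]], function(iv) {
            if (iv$span[1] >= pos) iv$span <- iv$span + length(toks)
            iv
          }),
          list(list(span = c(pos, pos + length(toks)), payload = payload)))
        invisible(NULL)
      }
      for (sp in gold) {
        if (stats::runif(1) < cfg$p_mention) {
          form <- sample(forms_of[[sp]], 1L)
          toks <- tokenize_text(form)
          si <- sample.int(n_sent, 1L)
          insert_at(si, toks, list(kind = "mention", species = sp,
                                   form = form, n_tokens = length(toks)))
        }
        for (cue in cues[[sp]]) {
          si <- sample.int(n_sent, 1L)
          insert_at(si, cue, list(kind = "cue", species = sp, cue = cue))
        }
      }
      planted_mentions <- list()
      planted_cues <- list()
      for (si in seq_len(n_sent)) {
        for (iv in planted[[si]]) {
          pl <- iv$payload
          if (pl$kind == "mention") {
            planted_mentions[[length(planted_mentions) + 1L]] <-
              list(species = pl$species, form = pl$form, sentence = si,
                   position = iv$span[1], n_tokens = pl$n_tokens)
          } else {
            planted_cues[[length(planted_cues) + 1L]] <-
              list(species = pl$species, cue = pl$cue, sentence = si,
                   position = iv$span[1])
          }
        }
      }
      doc_id <- sprintf("synth%05d", d)
      if (cfg$n_sections > 0L) {
        cut_points <- sort(sample.int(n_sent - 1L, min(cfg$n_sections - 1L,
                                                       n_sent - 1L)))
        groups <- findInterval(seq_len(n_sent) - 1L, cut_points) + 1L
        sections <- lapply(sort(unique(groups)), function(gix) list(
          title = sprintf("Section %d", gix),
          sentences = sents[groups == gix]))
        docs[[d]] <- seqc_document(doc_id, sections = sections, labels = gold)
      } else {
        docs[[d]] <- seqc_document(doc_id, abstract = sents, labels = gold)
      }
      manifest[[d]] <- list(doc_id = doc_id, labels = sort(gold),
                            mentions = planted_mentions, cues = planted_cues)
    }
    names(manifest) <- vapply(docs, `[[`, character(1), "doc_id")
    structure(list(docs = docs, manifest = manifest, cues = cues, cfg = cfg),
              class = "seqc_synth_corpus")
  })
}

#' @export
print.seqc_synth_corpus <- function(x, ...) {
  cat(sprintf("<seqc_synth_corpus: %d docs over %d species, p_mention=%.2f>\n",
              length(x$docs), length(x$cfg$species), x$cfg$p_mention))
  invisible(x)
}

#' Build a masked train/dev/test benchmark
#'
#' Generates a corpus with explicit mentions (`p_mention` must be positive),
#' verifies the dictionary annotation against the planted gold labels,
#' masks every mention with [SPECIES_MASK] — leaving cue tokens intact, so
#' labels must be inferred from context — and splits deterministically.
#'
#' @param cfg a [synthetic_config()] with `p_mention > 0`.
#' @param ratios train/dev/test ratios (default `c(0.75, 0.125, 0.125)`).
#' @param lex the lexicon used for annotation and masking.
#' @return list: `train`, `dev`, `test` (masked labeled documents),
#'   `manifest`, `cues`.
#' @export
make_masked_benchmark <- function(cfg, ratios = c(0.75, 0.125, 0.125),
                                  lex = compile_default_lexicon()) {
  if (cfg$p_mention <= 0)
    seqc_abort("config", "the masked benchmark needs p_mention > 0")
  corp <- generate_corpus(cfg, lex)
  masked <- mask_corpus(corp$docs, lex)
  parts <- split_corpus(masked, ratios, seed = derive_seed(cfg$seed, 7L))
  c(parts, list(manifest = corp$manifest, cues = corp$cues))
}
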