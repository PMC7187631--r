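---
title: "Classifying research species in neuroscience literature with sequence-to-sequence decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying research species in neuroscience literature with sequence-to-sequence decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A large share of neuroscience articles never state their model organism in
the abstract, yet almost every downstream use of the literature — linking
knowledge bases, building species-specific reviews, routing articles to the
right community — needs to know whether a study was done in mice, macaques,
zebrafish or humans. `seqspecies` implements a complete pipeline for this
task over a fixed inventory of 23 model organisms (mouse, rat, human,
zebrafish, *Drosophila melanogaster*, *C. elegans*, and so on):

1. **Dictionary regime.** When species are mentioned explicitly, a lexicon
   of surface forms (common names, frequent Latin names, plurals and
   variants) tags them directly (`find_mentions()`,
   `annotate_mention_labels()`).
2. **Inference regime.** When mentions are absent — or deliberately hidden
   by `mask_mentions()`, which replaces every mention with the single token
   `*SPECIES*` — a neural model must infer the species set from context:
   gene names, organs, methods, and other correlated vocabulary.

The inference model treats multi-label classification as sequence
generation: the document is encoded hierarchically and a decoder emits one
species label per step, terminating with an end symbol. This removes the
need for per-class probability thresholds (the usual weakness of binary
multi-label classifiers) and lets each prediction attend to its own span of
interest in the text.

## The model

**Label sequences.** A gold label set is rendered as a *virtual label
sequence*: labels sorted by descending training-set frequency (ties
alphabetical, zero-frequency labels appended alphabetically), wrapped in
`BOS`/`EOS`. Evaluation is on sets; order is discarded
(`from_label_sequence()`).

**Hierarchical encoder.** Each sentence (or, for full texts, each
discourse section) is run through a shared bidirectional LSTM; each token
keeps its concatenated forward/backward state \(h^{(e)}_{i,j}\in\mathbb
R^{\tau}\) and each unit its concatenated final states \(h^{(s)}_i\). A
second bidirectional LSTM over the unit vectors yields the document vector
\(h^{(doc)}\). With the default 100 hidden units per direction,
\(\tau = 200\) everywhere, which keeps the attention matrices square; this
resolves the tension between a per-direction size of 100 and 200-D
contextual vectors by reading the former as "per direction".

**Hierarchically attentive decoder.** A unidirectional LSTM emits labels.
At step \(t\), with pre-update hidden state \(h^{(d)}_{t-1}\):

- additive attention scores
  \(\mathrm{score}(h, q) = v^\top\tanh(W_1 h + W_2 q + b)\) are computed
  for every unit vector and every word state, with one shared parameter
  set;
- unit weights \(\beta_t = \mathrm{softmax}_i\,
  \mathrm{score}(h^{(s)}_i, h^{(d)}_{t-1})\);
- word weights are a *single global softmax* over all (unit, word) pairs
  of \(\beta_{t(i)}\cdot \mathrm{score}(h^{(e)}_{i,j}, h^{(d)}_{t-1})\),
  so the unit level gates the word level before normalisation;
- the context is \(c_t = \sum_{i,j}\alpha_{t(i,j)} h^{(e)}_{i,j}\).

The LSTM input at step \(t\) is the previous label's embedding
concatenated with the *previous* context \(c_{t-1}\) (with \(c_0 = 0\),
\(h^{(d)}_0 = h^{(doc)}\)); the defining equations attend with the
pre-update state while the cell consumes the previous context, and the
implementation follows them literally rather than re-attending after the
state update. Logits are \(W h^{(d)}_t + b + I_t\) where the mask \(I_t\)
removes already-predicted labels; numerically, masked entries are excluded
before exponentiation so their probability is exactly zero, not merely
tiny. EOS is never masked, and after all \(m\) labels have been emitted
only EOS remains, so decoding always terminates within \(m+1\) steps.

**Ablation modes** mirror the structural variants used to analyse the
architecture: `no_s_att` (one flat softmax over word scores), `no_w_att`
(attend to unit vectors only), `no_attention` (zero context). Attention
maps are defined in every mode so exports stay valid: in `no_w_att` the
unit weight is spread uniformly over the unit's words, in `no_s_att` the
unit weight is the within-unit sum of word weights, in `no_attention` both
are uniform. These conventions are this package's choice.

**Training** is teacher-forced cross-entropy: the per-document loss is the
mean step negative log-probability of the gold sequence, with the gold
previous label fed at each step and the no-repeat mask built from the gold
prefix. Batches average per-document losses (a constant factor relative to
summing, absorbed by the learning rate). Optimisation is Adam at 0.001
with dropout 0.5 on embeddings and the decoder input, up to 100 epochs by
default. Because batch composition and early stopping are not dictated by
the method itself, the package defaults to plain per-document stochastic
updates (batch size 1) — on the small corpora this implementation targets,
convergence is limited by optimizer-step count, so frequent updates beat
smoother batched gradients — and a dev micro-F1 patience of 10 epochs
(stopping immediately at 1.0, which cannot be improved); both are
configurable. For the same reason, initialisation follows the classic
LSTM recipe: forget-gate bias 1, gain-2 Glorot weights for all LSTM
matrices, embeddings uniform in ±0.5 — without these, early activations
vanish through the three stacked recurrences and training crawls. **Inference** is greedy or beam search
(default width 5 — a conventional value, as the method itself does not
prescribe one); finished beams are frozen and compete on total
log-probability without length normalisation, with ties broken toward
shorter label sets and then lexicographically.

The whole network — embeddings, both BiLSTM levels, attention, decoder —
runs on a small reverse-mode autodiff tape implemented in base R matrix
algebra (`R/autodiff.R`), with one fused operation for a masked, batched
LSTM sequence pass whose backward is hand-written backpropagation through
time. Analytic gradients are pinned to central finite differences on a
micro model (relative tolerance `1e-4` with an absolute floor of `1e-7`
for near-zero entries, where finite differences themselves lose
precision).

## Corpus construction

`parse_record()` reads a simplified XML record dialect (id, title,
abstract, keywords, dated, sectioned body). Full JATS support is
deliberately out of scope; tables are deleted wholesale and reference-like
sections (references, bibliography, acknowledgments, supplementary) are
dropped so none of their tokens pollute the text. `is_neuroscience()`
keeps documents where some token starts with one of
*brain, neuron, neural, neuro, cerebral* (case-insensitive, word-level),
checked over title, abstract and body.

Tokenisation is whitespace splitting with leading/trailing punctuation
stripped, internal hyphens and case preserved; the mask symbol
`*SPECIES*` is exempt from stripping so masked corpora survive text
round-trips. Sentence splitting is rule-based (`[.!?]` + space + capital
or digit, with an abbreviation stop-list) — deterministic by design, since
the pipeline must be reproducible.

**Full-category sampling** (`full_category_sample()`) builds
class-balanced datasets: shuffle, take the first *n* candidates (defaults
*n* = 50,000, support *s* = 400), scan once, and admit a document while
any of its labels is still below the per-class support cap. The
pseudocode is transliterated exactly: a label's tally increments only
while below *s*, a document is added at most once, unlabeled documents are
never added. The shuffle seed is recorded so sampled datasets are
reproducible. Splitting happens after sampling.

## The synthetic testbed

Real annotated corpora of this kind require bulk literature downloads, so
the package ships a generator (`generate_corpus()`,
`make_masked_benchmark()`) that emulates the two regimes. Documents are
filler sentences over an invented background vocabulary; each gold species
plants (a) a lexicon surface form with probability `p_mention` and (b) a
fixed number of species-specific *cue tokens* — invented words disjoint
from both the lexicon and the background vocabulary, standing in for the
genes/organs/functions that signal a species in real text. Masking removes
the mentions but not the cues, so a model must learn the cue-species
association exactly as it must learn contextual signals in real abstracts.
Insertions never split a previously planted multiword mention, and the
generation manifest records every planted position (verified token-exact
by the tests).

Generator defaults, chosen once as plausible for short abstracts:
per-species inclusion probability 0.3, 4–8 sentences per document,
sentence length 5–15 tokens, background vocabulary 200, at least one label
per document (rejection sampling).

The reference recovery benchmark used by the test suite: 600/100/100
train/dev/test masked documents over six species (Cat, Human, Monkey,
Mouse, Rat, Zebrafish), two cues per species, `p_mention = 1` then masked,
trained at reduced dimensions (word 32, hidden 32 per direction,
\(\tau = 64\), at most 30 epochs, fixed seeds) — small enough to run on
one CPU while exercising every component end to end. What passing shows:
the full pipeline (generation → masking → training → beam decoding →
evaluation) recovers planted structure almost perfectly. What it does not
show: performance on real literature, where cues are noisy, correlated and
unevenly distributed — the synthetic generator makes no attempt to emulate
real biomedical language or PubMed's class imbalance beyond the configured
label distribution.

## Evaluation

`evaluate_predictions()` reports Hamming loss (fraction of wrong label
slots over the full vocabulary), micro-averaged P/R/F1 (globally pooled
counts), macro-F1 (unweighted mean of per-class F1 over *every* vocabulary
class — "treats all classes equally" — with 0/0 conventions scored 0), and
document-averaged P/R/F1 (a document with empty gold and empty prediction
scores 1). These degenerate-case conventions are stated choices; the
metric definitions themselves do not fix them.

## Numerical and design notes

- Degenerate inputs: empty documents refuse to encode; empty label sets
  train on a single EOS step; sampling an empty corpus yields an empty
  sample.
- Truncation: sentences are capped at 128 tokens, sections at 512, and
  documents at 600 units, tail-first. Whether very long documents should
  be truncated or binned is ambiguous in general; truncation was chosen
  as the behaviour-preserving option for encoding.
- The word-vector loader accepts plain-text word2vec/GloVe files (optional
  header detected); pretrained tables are frozen during training, the
  randomly initialised table is trainable.
- Character features (25-D embeddings; width-3 CNN max-pooled to 100-D, or
  a 50-D-per-direction BiLSTM) are implemented but off by default: which
  variant the reference setup actually used is not stated, and word-level
  features suffice on the synthetic testbed.
- All randomness (init, shuffling, dropout, generation) flows from
  explicit seeds; library code restores the caller's RNG state.

## Limitations

- Pure-R training: practical for the reduced-dimension benchmark and for
  small corpora, not for multi-million-document collections or the full
  200-D configuration at scale.
- The shipped lexicon is an approximation assembled from common and Latin
  names with plurals; it is versioned and extendable (TSV), but it is not
  a taxonomy service, and word-sense ambiguity ("cricket" the game,
  "mouse" the device) is deliberately left to the model.
- Species normalisation to taxonomy identifiers, expert semantic
  annotation, and transformer baselines are out of scope.
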