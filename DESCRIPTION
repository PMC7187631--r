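Package: seqspecies
Title: Species Multi-Label Classification for Neuroscience Literature by
    Sequence-to-Sequence Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to tag, mask and classify the research species of
    neuroscience articles. Provides a 23-organism species lexicon with
    mention finding and masking, a full-category sampling algorithm for
    class-balanced corpus construction, a hierarchical bidirectional LSTM
    document encoder paired with a label-sequence decoder that uses
    hierarchical attentive decoding (two-level attention over
    sentences/sections and words) and a no-repeat label mask, beam-search
    inference, teacher-forced training with Adam, multi-label evaluation
    (Hamming loss, micro/macro-F1, per-document P/R/F1), and a synthetic
    corpus generator for controlled experiments. The neural components are
    implemented on an internal reverse-mode automatic differentiation tape.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
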