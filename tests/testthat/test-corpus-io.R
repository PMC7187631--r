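test_that("entity unescaping handles the standard table and is idempotent", {
  expect_equal(unescape_entities("a &amp; b"), "a & b")
  expect_equal(unescape_entities("no entities here"), "no entities here")
  expect_equal(unescape_entities("&lt;i&gt;&quot;x&quot;"), "<i>\"x\"")
  expect_equal(unescape_entities("&apos;y&apos; &#65; &#x42;"), "'y' A B")
  # malformed entities pass through
  expect_equal(unescape_entities("&unknown; &#;"), "&unknown; &#;")
  # idempotent on text without a raw ampersand
  for (x in c("plain", "<i>\"x\"", "a b c", "p<0.05")) {
    expect_identical(unescape_entities(x), x)
  }
})

test_that("tokenization strips edge punctuation, keeps internal hyphens and case", {
  expect_equal(tokenize_text("Neurons fire (fast)."), c("Neurons", "fire", "fast"))
  expect_equal(tokenize_text("the 5-HT receptor, N171-82Q!"),
               c("the", "5-HT", "receptor", "N171-82Q"))
  expect_equal(tokenize_text("*SPECIES* brains"), c("*SPECIES*", "brains"))
  expect_equal(tokenize_text("   "), character())
})

test_that("sentence splitting respects abbreviations and terminators", {
  s <- split_sentences("Mice run fast. They sleep a lot! Do they dream?")
  expect_length(s, 3)
  expect_equal(s[1], "Mice run fast.")
  s2 <- split_sentences("As shown by Smith et al. 2019 was key. A new era began.")
  expect_length(s2, 2)
  s3 <- split_sentences("See Fig. 3 for details. The rest follows.")
  expect_length(s3, 2)
  expect_equal(split_sentences("no terminal here"), "no terminal here")
})

test_that("parse_record extracts fields and drops tables and reference sections", {
  doc <- parse_record(record_xml())
  expect_s3_class(doc, "seqc_document")
  expect_equal(doc$doc_id, "12345")
  expect_equal(doc$title, c("A", "neural", "study"))
  expect_length(doc$abstract, 2)
  expect_length(doc$sections, 0)
  expect_equal(doc$keywords, c("brain", "memory"))
  expect_equal(doc$date, "2019-05-01")

  body <- paste0(
    "<body>",
    '<section title="Methods">We measured spikes. ',
    "<table>p&lt;0.05 significance</table>Signals were clean.</section>",
    '<section title="Results">Neurons responded.</section>',
    '<section title="References">Smith 2001. Jones 2002.</section>',
    "</body>")
  doc2 <- parse_record(record_xml(id = "77", body = body))
  expect_length(doc2$sections, 2)
  expect_equal(vapply(doc2$sections, `[[`, character(1), "title"),
               c("Methods", "Results"))
  toks <- doc_tokens(doc2)
  expect_false(any(grepl("significance", toks)))
  expect_false(any(toks == "p<0.05"))
  expect_false(any(toks == "Smith"))
})

test_that("parse_record fails on missing id or empty content", {
  expect_error(parse_record("<record><title>t</title></record>"),
               class = "seqspecies_parse_error")
  expect_error(parse_record(record_xml(id = "9", title = "", abstract = "")),
               class = "seqspecies_parse_error")
})

test_that("neuroscience filter is a word-level case-insensitive prefix match", {
  expect_true(is_neuroscience(make_doc("a", list("the Neurons fire"))))
  expect_true(is_neuroscience(make_doc("b", list("lesions of the brainstem"))))
  expect_false(is_neuroscience(make_doc("c", list("cardiac muscle tissue"))))
  # monotone: adding a matching token never flips true -> false
  d <- make_doc("d", list("cardiac muscle"))
  d2 <- make_doc("d2", list("cardiac muscle", "neural crest"))
  expect_false(is_neuroscience(d))
  expect_true(is_neuroscience(d2))
  expect_error(is_neuroscience(d, character()), class = "seqspecies_config_error")
})

test_that("JSONL round-trip reproduces documents field-for-field", {
  docs <- list(
    make_doc("d1", list("the Mouse ran", "it stopped"), labels = c("Mouse")),
    seqc_document("d2", title = tokenize_text("A neural title"),
                  abstract = list(tokenize_text("one sentence only")),
                  sections = list(list(title = "Methods",
                                       sentences = list(tokenize_text("we did things")))),
                  keywords = c("brain"), date = "2020-01-01"),
    mask_mentions(make_doc("d3", list("rats and mice here")), the_lexicon))
  path <- tempfile(fileext = ".jsonl")
  write_jsonl(docs, path)
  back <- read_jsonl(path)
  expect_length(back, 3)
  for (i in seq_along(docs)) {
    for (f in c("doc_id", "title", "abstract", "sections", "keywords",
                "date", "labels", "masked"))
      expect_identical(back[[i]][[f]], docs[[i]][[f]], label = sprintf("doc %d field %s", i, f))
  }
  # empty corpus round-trips
  write_jsonl(list(), path)
  expect_length(read_jsonl(path), 0)
})

test_that("JSONL schema errors name the offending line", {
  path <- tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"a","title":"t","abstract":["x y"]}',
               '{"title":"no id","abstract":["x"]}'), path)
  err <- expect_error(read_jsonl(path), class = "seqspecies_schema_error")
  expect_match(conditionMessage(err), "line 2")
})
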