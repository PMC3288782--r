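test_that("phrases_in_order gives global document order", {
  rows <- dplyr::bind_rows(
    phrase_row("s0.p0", 0L, 0L, "NP", "alpha"),
    phrase_row("s0.p1", 0L, 1L, "NP", "beta"),
    phrase_row("s1.p0", 1L, 0L, "NP", "gamma"),
    phrase_row("s1.p1", 1L, 1L, "NP", "delta"))
  doc <- drug_document("d", tibble::tibble(index = 0:1, text = c("a b.", "c d.")),
                       rows)
  expect_equal(phrases_in_order(doc)$id, c("s0.p0", "s0.p1", "s1.p0", "s1.p1"))

  empty <- drug_document("e", tibble::tibble(index = integer(), text = character()),
                         phrase_row("x", 0L, 0L, "NP", "x")[0, ])
  expect_equal(nrow(phrases_in_order(empty)), 0L)
})

test_that("validation rejects duplicate IDs and non-preceding antecedents", {
  rows <- dplyr::bind_rows(
    phrase_row("s0.p0", 0L, 0L, "NP", "alpha"),
    phrase_row("s0.p0", 0L, 1L, "NP", "beta"))
  expect_error(
    drug_document("d", tibble::tibble(index = 0L, text = "x."), rows),
    "duplicate")

  rows2 <- dplyr::bind_rows(
    phrase_row("s0.p0", 0L, 0L, "NP", token_tibble("it", pos = "PRON")),
    phrase_row("s0.p1", 0L, 1L, "NP", "warfarin"))
  gold_bad <- tibble::tibble(anaphor_id = "s0.p0",
                             antecedent_ids = list("s0.p1"),
                             category = "pronominal", subclass = "personal")
  expect_error(
    drug_document("d", tibble::tibble(index = 0L, text = "x."), rows2, gold_bad),
    "precede")
})

test_that("an annotated record round-trips through JSON and XML", {
  ex <- reference_examples()
  doc <- ex$documents$ex_annotated_sentence

  # the published phrase record survives the trip with all its fields
  p369 <- doc$phrases[doc$phrases$id == "s28.p369", ]
  expect_equal(p369$text, "with aprazolam")
  expect_equal(p369$cui, "C0002333")
  expect_setequal(p369$semtypes[[1]], c("orch", "phsu"))

  for (fmt in c("json", "xml")) {
    tf <- tempfile(fileext = paste0(".", fmt))
    write_document(doc, tf, format = fmt)
    back <- read_document(tf, format = fmt)
    expect_equal(back$doc_id, doc$doc_id)
    expect_equal(back$phrases, doc$phrases)
    expect_equal(back$gold, doc$gold)
    expect_equal(back$sentences$text, doc$sentences$text)
  }
})

test_that("serialize-parse is the identity on generated documents", {
  corp <- generate_corpus(n_documents = 2, sentences_per_document = 8, seed = 11)
  for (doc in corp$documents) {
    tf <- tempfile(fileext = ".json")
    write_document(doc, tf)
    back <- read_document(tf)
    expect_equal(back$phrases, doc$phrases)
    expect_equal(back$gold$antecedent_ids, doc$gold$antecedent_ids)
  }
})

test_that("writing links with dangling IDs is an integrity error", {
  doc <- annotate_text("Fluoxetine inhibits CYP2D6.")
  bad <- tibble::tibble(doc_id = doc$doc_id, anaphor_id = "nope",
                        category = "pronominal", subclass = "personal",
                        strategy = "centering", resolved = TRUE,
                        antecedent_ids = list("s0.p1"))
  expect_error(write_document(doc, tempfile(), links = bad), "unknown phrase id")
})

test_that("malformed files raise schema errors naming the element", {
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(sentences = list()), tf, auto_unbox = TRUE)
  expect_error(read_document(tf), "doc_id")
  tf2 <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(doc_id = "d",
         sentences = list(list(index = 0, text = "x",
                               phrases = list(list(type = "NP"))))),
    tf2, auto_unbox = TRUE)
  expect_error(read_document(tf2), "id")
})

test_that("an empty document reads back as empty", {
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(doc_id = "empty", source = "", sentences = list(),
                            gold = list()),
                       tf, auto_unbox = TRUE)
  doc <- read_document(tf)
  expect_equal(nrow(doc$sentences), 0L)
  expect_equal(nrow(doc$phrases), 0L)
})
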