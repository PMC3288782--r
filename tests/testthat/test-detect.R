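mk <- function(text) annotate_text(text)

test_that("pleonastic-it patterns match the canonical sentences", {
  lex <- default_lexicon()
  cases <- list(
    c("It is not known whether other progestational contraceptives are adequate methods of contraception.", TRUE),
    c("If it is not possible to discontinue the diuretic, the starting dose should be reduced.", TRUE),
    c("It does not appear that the SSRIs reduce the effectiveness of a mood stabilizer.", TRUE),
    c("Patients should stop treatment because it inhibits CYP3A4.", FALSE))
  for (cs in cases) {
    tok <- pos_tag(tokenize_text(cs[[1]]), lex)
    it_pos <- which(tolower(tok$text) == "it")[1]
    expect_equal(is_pleonastic_it(tok, it_pos), as.logical(cs[[2]]), label = cs[[1]])
  }
})

test_that("pleonastic and second-person pronouns yield no mentions", {
  doc <- mk("It is not known whether warfarin interacts with aspirin.")
  m <- detect_anaphors(doc)
  expect_false(any(m$category == "pronominal"))

  doc2 <- mk("You should ask your doctor before combining these treatments.")
  expect_equal(nrow(detect_anaphors(doc2)), 0L)
})

test_that("correlative constructions are recognised and excluded", {
  doc <- mk("These effects can result in prolonged sedation of both midazolam and triazolam.")
  both_id <- doc$phrases$id[grepl("^of both", doc$phrases$text)]
  tok <- doc$phrases$tokens[[match(both_id, doc$phrases$id)]]
  expect_true(is_correlative(doc, both_id, which(tolower(tok$text) == "both")))
  expect_equal(nrow(detect_anaphors(doc)), 0L)

  doc2 <- mk("Fluoxetine and paroxetine interact; both drugs should be monitored.")
  bd <- doc2$phrases$id[grepl("both drugs", doc2$phrases$text)]
  expect_false(is_correlative(doc2, bd, 1L))
  m2 <- detect_anaphors(doc2)
  expect_true(any(m2$subclass == "distributive" & m2$category == "nominal"))

  doc3 <- mk("Either cimetidine or ranitidine may be used.")
  eid <- doc3$phrases$id[grepl("^Either", doc3$phrases$text)]
  expect_true(is_correlative(doc3, eid, 1L))
  expect_equal(nrow(detect_anaphors(doc3)), 0L)
})

test_that("nominal candidates need a drug-denoting head; specific drug
           names and bare property nouns are disregarded", {
  m <- detect_anaphors(mk("Warfarin interacts with heparin. These anticoagulants should be monitored."))
  expect_true(any(m$category == "nominal" & m$subclass == "demonstrative"))

  m2 <- detect_anaphors(mk("Patients often receive warfarin. The aspirin should be stopped."))
  expect_false(any(m2$category == "nominal"))

  m3 <- detect_anaphors(mk("Fluoxetine should be monitored because of its pharmacological effects."))
  expect_equal(m3$subclass[m3$category == "nominal"], "possessive")
  # possessive number comes from the possessor, not the head noun
  expect_equal(m3$number[m3$subclass == "possessive"], "singular")
})

test_that("coordination detection groups comma/conjunction lists", {
  doc <- mk("fluoxetine, sertraline and paroxetine inhibit P450 2D6.")
  co <- detect_coordinations(doc)
  expect_equal(nrow(co), 1L)
  expect_length(co$member_ids[[1]], 3L)

  doc2 <- mk("Fluoxetine inhibits CYP2D6 in most patients.")
  expect_equal(nrow(detect_coordinations(doc2)), 0L)
})

test_that("detection is deterministic, idempotent, and never doubles a
           mention across categories", {
  corp <- generate_corpus(n_documents = 2, sentences_per_document = 10,
                          distractor_rate = 0.5, seed = 5)
  for (doc in corp$documents) {
    m1 <- detect_anaphors(doc)
    m2 <- detect_anaphors(doc)
    expect_equal(m1, m2)
    expect_equal(anyDuplicated(m1$phrase_id), 0L)
  }
})

test_that("relative vs demonstrative 'that' follows the clause rule", {
  m <- detect_anaphors(mk("Patients receiving digoxin that inhibits the sodium pump should be monitored."))
  expect_true(any(m$subclass == "relative" & m$unit == "that"))
})
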