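test_that("tokenizer splits words, protects abbreviations, covers text", {
  tok <- tokenize_text("they might increase dofetilide levels")
  expect_equal(nrow(tok), 5L)
  expect_equal(tok$text[1], "they")

  expect_equal(nrow(tokenize_text("")), 0L)

  tok2 <- tokenize_text("e.g., prolonged")
  expect_equal(tok2$text, c("e.g.", ",", "prolonged"))

  # offsets are 0-based half-open and substrings match token text
  txt <- "Caution is advised with fluoxetine, which inhibits CYP2D6."
  tok3 <- tokenize_text(txt)
  expect_true(all(tok3$start < tok3$end))
  for (i in seq_len(nrow(tok3))) {
    expect_equal(substr(txt, tok3$start[i] + 1, tok3$end[i]), tok3$text[i])
  }
})

test_that("chunker emits the expected phrases with rightmost-noun heads", {
  lex <- default_lexicon()
  ch <- chunk_tokens(pos_tag(tokenize_text("with aprazolam"), lex), lex)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$type, "PP")
  expect_equal(ch$tokens[[1]]$text[ch$head_index], "aprazolam")

  ch2 <- chunk_tokens(pos_tag(tokenize_text("its pharmacological effects"), lex), lex)
  expect_equal(ch2$type, "NP")
  expect_equal(ch2$tokens[[1]]$text[ch2$head_index], "effects")

  ch3 <- chunk_tokens(pos_tag(tokenize_text("warfarin"), lex), lex)
  expect_equal(ch3$type, "NP")
  expect_equal(nrow(ch3$tokens[[1]]), 1L)
})

test_that("every token lands in exactly one chunk", {
  lex <- default_lexicon()
  texts <- c(
    "In addition triamterene, metformin and amiloride should be co-administered with care as they might increase dofetilide levels.",
    "It is not known whether other progestational contraceptives are adequate.",
    "Either cimetidine or ranitidine may be used as monotherapy.")
  for (txt in texts) {
    tok <- pos_tag(tokenize_text(txt), lex)
    ch <- chunk_tokens(tok, lex)
    covered <- unlist(purrr::map(ch$tokens, function(t) t$text))
    expect_equal(covered, tok$text)
  }
})

test_that("attach_semantics populates concepts from the lexicon", {
  lex <- default_lexicon()
  pp <- phrase_row("s0.p1", 0L, 0L, "PP",
                   token_tibble(c("with", "aprazolam"), pos = c("PREP", "NOUN")))
  got <- attach_semantics(pp, lex)
  expect_equal(got$cui, "C0002333")
  expect_equal(got$concept, "Alprazolam")
  expect_setequal(got$semtypes[[1]], c("orch", "phsu"))

  np <- phrase_row("s0.p2", 0L, 1L, "NP",
                   token_tibble(c("the", "table"), pos = c("DET", "NOUN")))
  same <- attach_semantics(np, lex)
  expect_true(is.na(same$cui))
  expect_length(same$semtypes[[1]], 0L)

  qn <- phrase_row("s0.p3", 0L, 2L, "NP",
                   token_tibble(c("its", "pharmacological", "effects"),
                                pos = c("DET", "ADJ", "NOUN")))
  expect_true("qlco" %in% attach_semantics(qn, lex)$semtypes[[1]])
})

test_that("INN affix classification picks the longest matching stem", {
  expect_equal(classify_inn_affix("aprazolam"), "Benzodiazepine derivative")
  expect_true(is.na(classify_inn_affix("zzzz")))
  tab <- default_affix_table()
  expect_equal(classify_inn_affix("propranolol"),
               tab$family[tab$suffix == "olol"])
  # -prazole must beat -azole
  expect_equal(classify_inn_affix("omeprazole"),
               tab$family[tab$suffix == "prazole"])
  expect_equal(classify_inn_affix("ketoconazole"),
               tab$family[tab$suffix == "azole"])
  # property: for random words the longest applicable suffix wins
  withr::with_seed(42, {
    for (k in 1:50) {
      stem <- paste(sample(letters, 4), collapse = "")
      suf <- sample(tab$suffix, 1)
      fam <- classify_inn_affix(paste0(stem, suf))
      applicable <- tab$suffix[endsWith(paste0(stem, suf), tab$suffix)]
      longest <- applicable[which.max(nchar(applicable))]
      expect_equal(fam, tab$family[tab$suffix == longest])
    }
  })
})

test_that("grammatical number follows the lexical patterns with the
           singular exception taking precedence", {
  expect_equal(grammatical_number("INHIBITORS"), "plural")
  expect_equal(grammatical_number("FLUVOXAMINE"), "singular")
  expect_equal(grammatical_number("BOLUS"), "singular")
  expect_equal(grammatical_number("effects"), "plural")
  # every word matching the exception is singular even if it also matches
  # the plural pattern
  withr::with_seed(7, {
    for (k in 1:40) {
      w <- paste0(paste(sample(LETTERS, 5), collapse = ""),
                  sample(c("US", "SS"), 1))
      expect_equal(grammatical_number(w), "singular")
    }
  })
})

test_that("the full pipeline produces a valid annotated document", {
  doc <- annotate_text(paste(
    "In addition triamterene, metformin and amiloride should be",
    "co-administered with care as they might increase dofetilide levels."))
  expect_silent(validate_document(doc))
  ph <- phrases_in_order(doc)
  drugs <- ph[!is.na(ph$cui), ]
  expect_true(all(c("triamterene", "metformin", "amiloride") %in%
                    tolower(drugs$head)))
  pron <- ph[ph$text == "they", ]
  expect_equal(nrow(pron), 1L)
  expect_equal(pron$tokens[[1]]$pos, "PRON")

  expect_equal(nrow(annotate_text("")$sentences), 0L)

  doc2 <- annotate_text("Coadministration with alprazolam is not recommended.")
  alz <- doc2$phrases[grepl("alprazolam", doc2$phrases$text), ]
  expect_setequal(alz$semtypes[[1]], c("orch", "phsu"))
  expect_equal(alz$drug_family, "Benzodiazepine derivative")
})

test_that("token coverage is preserved through annotate_text", {
  corp <- generate_corpus(n_documents = 1, sentences_per_document = 10, seed = 3)
  doc <- corp$documents[[1]]
  for (si in doc$sentences$index) {
    ph <- doc$phrases[doc$phrases$sentence == si, ]
    phrase_tokens <- unlist(purrr::map(ph$tokens, function(t) t$text))
    sent_tokens <- tokenize_text(doc$sentences$text[si + 1])$text
    expect_equal(phrase_tokens, sent_tokens)
  }
})
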