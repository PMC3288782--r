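test_that("center lists follow the centering order and collapse
           coordinations", {
  doc <- annotate_text(paste(
    "Triamterene, metformin and amiloride should be co-administered",
    "with care as they might increase dofetilide levels."))
  m <- detect_anaphors(doc)
  cs <- build_center_list(doc, m$phrase_id[1])
  expect_true(nrow(cs) >= 1)
  # the coordination is one center and comes first (leftmost)
  expect_length(cs$member_ids[[1]], 3L)
  expect_true(cs$is_group[1])
  expect_equal(cs$number[1], "plural")
  # members never appear both individually and as a group
  singles <- unlist(cs$member_ids[!cs$is_group])
  expect_length(intersect(singles, cs$member_ids[[1]]), 0L)
})

test_that("an anaphor with nothing before it gets an empty center list", {
  rows <- phrase_row("s0.p0", 0L, 0L, "NP", token_tibble("it", pos = "PRON"),
                     number = "singular")
  doc <- drug_document("d", tibble::tibble(index = 0L, text = "It."), rows)
  expect_equal(nrow(build_center_list(doc, "s0.p0")), 0L)
})

test_that("with no same-sentence nominals the previous sentence is
           searched left to right", {
  rows <- dplyr::bind_rows(
    phrase_row("s0.p0", 0L, 0L, "NP", "warfarin", cui = "C1",
               semtypes = "phsu", number = "singular"),
    phrase_row("s0.p1", 0L, 1L, "NP", "digoxin", cui = "C2",
               semtypes = "phsu", number = "singular"),
    phrase_row("s1.p0", 1L, 0L, "NP", token_tibble("it", pos = "PRON"),
               number = "singular"))
  doc <- drug_document("d", tibble::tibble(index = 0:1, text = c("a.", "b.")),
                       rows)
  cs <- build_center_list(doc, "s1.p0")
  expect_equal(unlist(cs$member_ids), c("s0.p0", "s0.p1"))
})

test_that("agreement checks number, drug semantic type and specificity", {
  they <- tibble::tibble(category = "pronominal", subclass = "personal",
                         unit = "they", number = "plural")
  it <- tibble::tibble(category = "pronominal", subclass = "personal",
                       unit = "it", number = "singular")
  nom <- tibble::tibble(category = "nominal", subclass = "demonstrative",
                        unit = "these", number = "plural")
  group3 <- tibble::tibble(member_ids = list(c("a", "b", "c")), sentence = 0L,
                           first_pos = 0L, last_pos = 2L, number = "plural",
                           semtypes = list("phsu"), specific = TRUE,
                           is_group = TRUE, cardinality = 3L)
  plural_np <- dplyr::mutate(group3, is_group = FALSE, cardinality = 1L)
  abstract <- dplyr::mutate(plural_np, specific = FALSE)
  nondrug <- dplyr::mutate(plural_np, semtypes = list("qlco"))

  expect_true(agrees(they, group3))
  expect_false(agrees(it, plural_np))        # number clash
  expect_true(agrees(they, plural_np))       # plural pronoun vs plural NP
  expect_false(agrees(nom, abstract))        # abstract center for nominal
  expect_true(agrees(nom, group3))
  expect_false(agrees(they, nondrug))        # semantic filter on pronouns
  expect_true(agrees(they, nondrug, semantic_filter_pronouns = FALSE))

  both <- tibble::tibble(category = "pronominal", subclass = "distributive",
                         unit = "both", number = "plural")
  expect_false(agrees(both, group3))         # 'both' needs cardinality 2
  group2 <- dplyr::mutate(group3, member_ids = list(c("a", "b")),
                          cardinality = 2L)
  expect_true(agrees(both, group2))
  each <- dplyr::mutate(both, unit = "each", number = "singular")
  expect_true(agrees(each, group3))
})

test_that("the baseline takes the closest nominal with no agreement", {
  doc <- annotate_text(paste(
    "Triamterene, metformin and amiloride should be co-administered",
    "with care as they might increase dofetilide levels."))
  links <- resolve_anaphora(doc, strategy = "baseline")
  expect_equal(nrow(links), 1L)
  # a single phrase to the left, not the coordination group
  expect_length(links$antecedent_ids[[1]], 1L)
  expect_equal(doc$phrases$text[match(links$antecedent_ids[[1]],
                                      doc$phrases$id)], "with care")
})

test_that("relative, reflexive and possessive anaphors go to the local
           strategy, others to centering", {
  doc <- annotate_text(paste(
    "Caution is advised with fluoxetine, which inhibits CYP2D6.",
    "Warfarin itself does not alter hepatic metabolism.",
    "Digoxin and verapamil should not be combined because of their",
    "additive effects. Ketoconazole inhibits CYP3A4. It raises",
    "midazolam exposure."))
  links <- resolve_anaphora(doc)
  by_sub <- stats::setNames(links$strategy, links$subclass)
  expect_equal(unname(by_sub["relative"]), "local")
  expect_equal(unname(by_sub["reflexive"]), "local")
  expect_equal(unname(by_sub["possessive"]), "local")
  expect_equal(unname(by_sub["personal"]), "centering")
  # the local matches land on the nearest agreeing drug
  rel <- links[links$subclass == "relative", ]
  expect_equal(tolower(doc$phrases$head[match(rel$antecedent_ids[[1]],
                                              doc$phrases$id)]), "fluoxetine")
  refl <- links[links$subclass == "reflexive", ]
  expect_equal(tolower(doc$phrases$head[match(refl$antecedent_ids[[1]],
                                              doc$phrases$id)]), "warfarin")
  poss <- links[links$subclass == "possessive", ]
  expect_length(poss$antecedent_ids[[1]], 2L)
})

test_that("a document with only pleonastic it yields no links, an empty
           document none", {
  doc <- annotate_text("It is not known whether the interaction is clinically relevant.")
  expect_equal(nrow(resolve_anaphora(doc)), 0L)
  empty <- annotate_text("")
  expect_equal(nrow(resolve_anaphora(empty)), 0L)
})

test_that("resolved links always satisfy exactly-one, precedence,
           two-sentence locality and agreement soundness", {
  corp <- generate_corpus(n_documents = 4, sentences_per_document = 14,
                          distractor_rate = 0.4, seed = 9)
  for (doc in corp$documents) {
    links <- resolve_anaphora(doc)
    mentions <- detect_anaphors(doc)
    coords <- detect_coordinations(doc)
    rank <- stats::setNames(seq_len(nrow(doc$phrases)), phrases_in_order(doc)$id)
    sent <- stats::setNames(doc$phrases$sentence, doc$phrases$id)
    grouped <- coords$member_ids
    for (i in seq_len(nrow(links))) {
      if (!links$resolved[i]) next
      ants <- links$antecedent_ids[[i]]
      # exactly one center: a singleton or exactly one coordination group
      if (length(ants) > 1) {
        expect_true(any(purrr::map_lgl(grouped, function(g) setequal(g, ants))))
      }
      expect_true(all(rank[ants] < rank[links$anaphor_id[i]]))
      expect_true(all(sent[ants] %in%
                        c(sent[links$anaphor_id[i]], sent[links$anaphor_id[i]] - 1L)))
      # agreement soundness for the rule strategies
      m <- mentions[mentions$phrase_id == links$anaphor_id[i], ]
      cs <- build_center_list(doc, links$anaphor_id[i], coords, mentions)
      hit <- which(purrr::map_lgl(cs$member_ids, function(x) setequal(x, ants)))
      expect_length(hit, 1L)
      expect_true(agrees(m, cs[hit, ]))
    }
  }
})

test_that("unresolved when no agreeing center exists in scope", {
  rows <- dplyr::bind_rows(
    phrase_row("s0.p0", 0L, 0L, "NP", "placebo", number = "singular"),
    phrase_row("s0.p1", 0L, 1L, "NP", token_tibble("it", pos = "PRON"),
               number = "singular"))
  doc <- drug_document("d", tibble::tibble(index = 0L, text = "x."), rows)
  links <- resolve_anaphora(doc)
  expect_equal(nrow(links), 1L)
  expect_false(links$resolved[1])
})
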