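mk_gold <- function(n, doc = "d") {
  tibble::tibble(doc_id = doc, anaphor_id = paste0("a", seq_len(n)),
                 antecedent_ids = purrr::map(seq_len(n), function(i) paste0("x", i)),
                 category = "pronominal", subclass = "personal")
}
mk_links <- function(gold, correct = nrow(gold)) {
  l <- tibble::tibble(
    doc_id = gold$doc_id, anaphor_id = gold$anaphor_id,
    category = gold$category, subclass = gold$subclass,
    strategy = "centering", resolved = TRUE,
    antecedent_ids = gold$antecedent_ids)
  if (correct < nrow(gold)) {
    for (i in (correct + 1):nrow(gold)) l$antecedent_ids[[i]] <- "wrong"
  }
  l
}

test_that("perfect agreement scores P = R = F = 1", {
  g <- mk_gold(5)
  ev <- score_links(mk_links(g), g)
  expect_equal(ev$global$precision, 1)
  expect_equal(ev$global$recall, 1)
  expect_equal(ev$global$f, 1)
})

test_that("nothing resolved gives R = 0 and the P = 0 convention", {
  g <- mk_gold(3)
  none <- dplyr::mutate(mk_links(g), resolved = FALSE,
                        antecedent_ids = list(character(), character(), character()))
  ev <- score_links(none, g)
  expect_equal(ev$global$recall, 0)
  expect_equal(ev$global$precision, 0)
  expect_equal(ev$global$f, 0)
})

test_that("recall is correct over gold and strict set equality is
           required", {
  g <- mk_gold(10)
  ev <- score_links(mk_links(g, correct = 7), g)
  expect_equal(ev$global$recall, 0.7)
  expect_equal(ev$global$correct, 7)
  # partial overlap on a coordination center counts as wrong
  g2 <- mk_gold(1)
  g2$antecedent_ids[[1]] <- c("x1", "x2")
  l2 <- mk_links(g2)
  l2$antecedent_ids[[1]] <- "x1"
  expect_equal(score_links(l2, g2)$global$correct, 0)
})

test_that("balanced F is the harmonic mean with the zero convention", {
  expect_equal(round(f_score(0.84, 0.70), 2), 0.76)
  expect_equal(round(f_score(0.76, 1), 2), 0.86)
  expect_equal(f_score(0, 0), 0)
  for (x in c(0.1, 0.5, 0.93)) expect_equal(f_score(x, x), x)
  p <- runif(20); r <- runif(20)
  f <- f_score(p, r)
  expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
})

test_that("increment is relative gain with an infinity sentinel", {
  expect_equal(round(f_increment(0.76, 0.44), 2), 0.73)
  expect_equal(f_increment(0.5, 0.5), 0)
  expect_equal(round(f_increment(0.86, 0.18), 2), 3.78)
  expect_true(is.infinite(f_increment(0.3, 0)))
  expect_equal(f_increment(0, 0), 0)
})

test_that("the report is internally consistent and carries the infinity
           sentinel for zero baselines", {
  corp <- generate_corpus(n_documents = 3, sentences_per_document = 12,
                          distractor_rate = 0.6, seed = 21)
  lc <- resolve_corpus(corp, "centering")
  lb <- resolve_corpus(corp, "baseline")
  rep <- coref_report(score_links(lb, corp$gold), score_links(lc, corp$gold))
  t <- tidy(rep)
  expect_equal(t$f_approach, f_score(t$p_approach, t$r_approach))
  expect_equal(t$f_baseline, f_score(t$p_baseline, t$r_baseline))
  zero_rows <- t$f_baseline == 0 & t$f_approach > 0
  expect_true(all(is.infinite(t$increment[zero_rows])))
  # global counts equal the sum of per-class counts
  ev <- score_links(lc, corp$gold)
  expect_equal(sum(ev$by_class$n_gold), ev$global$n_gold)
  expect_equal(sum(ev$by_class$correct), ev$global$correct)
})

test_that("scoring is invariant to prediction order and document order", {
  corp <- generate_corpus(n_documents = 2, sentences_per_document = 10, seed = 13)
  links <- resolve_corpus(corp, "centering")
  ev1 <- score_links(links, corp$gold)
  shuffled <- links[withr::with_seed(1, sample(nrow(links))), ]
  ev2 <- score_links(shuffled, corp$gold)
  expect_equal(ev1$global, ev2$global)
  expect_equal(ev1$by_class, ev2$by_class)
})

test_that("mismatched document IDs raise an input error naming the
           offender", {
  g <- mk_gold(2)
  l <- mk_links(g)
  l$doc_id[2] <- "other_doc"
  expect_error(score_links(l, g, doc_ids = "d"), "other_doc")
})

test_that("tidy/glance/autoplot methods work on evaluation objects", {
  g <- mk_gold(4)
  ev <- score_links(mk_links(g, correct = 3), g)
  td <- tidy(ev)
  expect_true("global" %in% td$subclass)
  expect_equal(nrow(glance(ev)), 1L)
  rep <- coref_report(ev, ev)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
})
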