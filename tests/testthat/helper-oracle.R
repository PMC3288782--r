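# Hand-built small documents and an independent brute-force resolver used
# as the oracle for the centering search.

drug_semtype_sets <- list(c("orch", "phsu"), c("antb"), c("phsu"),
                          c("qlco"), character())

# A candidate phrase: possibly a drug (CUI + drug semtype), possibly plural.
random_candidate <- function(id, sentence, pos) {
  nm <- paste0("cand", sentence, "x", pos)
  is_drug <- runif(1) < 0.6
  semtypes <- if (is_drug) drug_semtype_sets[[sample(1:3, 1)]] else
    drug_semtype_sets[[sample(4:5, 1)]]
  number <- sample(c("singular", "plural"), 1)
  type <- sample(c("NP", "PP"), 1)
  toks <- if (type == "PP") {
    token_tibble(c("of", nm), pos = c("PREP", "NOUN"))
  } else token_tibble(nm, pos = "NOUN")
  phrase_row(id, sentence, pos, type, toks,
             cui = if (is_drug) paste0("C", sentence, pos) else NA_character_,
             semtypes = semtypes, number = number)
}

anaphor_specs <- list(
  list(kind = "pron", word = "it", number = "singular"),
  list(kind = "pron", word = "they", number = "plural"),
  list(kind = "nom", toks = c("the", "drug"), number = "singular"),
  list(kind = "nom", toks = c("these", "drugs"), number = "plural"))

# Two sentences; candidates spread over both; the anaphor ends sentence 1.
random_small_doc <- function(doc_id = "orc") {
  k0 <- sample(0:3, 1)
  k1 <- sample(0:3, 1)
  rows <- list()
  for (p in seq_len(k0)) {
    rows[[length(rows) + 1]] <- random_candidate(sprintf("s0.p%d", p), 0L, p - 1L)
  }
  for (p in seq_len(k1)) {
    rows[[length(rows) + 1]] <- random_candidate(sprintf("s1.p%d", p), 1L, p - 1L)
  }
  spec <- anaphor_specs[[sample(length(anaphor_specs), 1)]]
  ana <- if (spec$kind == "pron") {
    phrase_row(sprintf("s1.p%d", k1 + 1L), 1L, k1, "NP",
               token_tibble(spec$word, pos = "PRON"), number = spec$number)
  } else {
    phrase_row(sprintf("s1.p%d", k1 + 1L), 1L, k1, "NP",
               token_tibble(spec$toks, pos = c("DET", "NOUN")),
               number = spec$number)
  }
  rows[[length(rows) + 1]] <- ana
  doc <- drug_document(
    doc_id,
    tibble::tibble(index = 0:1, text = c("filler.", "filler.")),
    dplyr::bind_rows(rows))
  list(doc = doc, anaphor_id = ana$id,
       category = if (spec$kind == "pron") "pronominal" else "nominal")
}

# Independent re-implementation: enumerate candidates in the stated order
# (same sentence left to right before the anaphor, then the previous
# sentence left to right) and return the first that satisfies the number,
# drug-semantic-type and specificity constraints.
brute_force_centering <- function(doc, anaphor_id, category) {
  ph <- phrases_in_order(doc)
  ai <- match(anaphor_id, ph$id)
  a <- ph[ai, ]
  same <- ph[ph$sentence == a$sentence & ph$pos < a$pos, , drop = FALSE]
  prev <- ph[ph$sentence == a$sentence - 1L, , drop = FALSE]
  generic_or_family <- c(coref_terms()$generic_drug_terms,
                         coref_terms()$family_nouns)
  for (cand in list(same, prev)) {
    for (j in seq_len(nrow(cand))) {
      num_ok <- a$number == "unknown" || cand$number[j] == "unknown" ||
        a$number == cand$number[j]
      sem_ok <- length(intersect(cand$semtypes[[j]],
                                 c("phsu", "antb", "clnd"))) > 0
      spec_ok <- category != "nominal" ||
        ((!is.na(cand$cui[j]) || !is.na(cand$drug_family[j])) &&
           !tolower(cand$head[j]) %in% generic_or_family)
      if (num_ok && sem_ok && spec_ok) return(cand$id[j])
    }
  }
  NA_character_
}
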