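# Phase 1: identification of anaphoric expressions. Pronominal and nominal
# candidate selection over the chunked document, with pleonastic-it and
# correlative filters and coordination detection.

PRONOMINAL_INVENTORY <- list(
  personal = c("it", "they"),
  reflexive = c("itself", "themselves"),
  relative = c("which", "that"),
  distributive = c("both", "each", "either", "neither"),
  demonstrative = c("these", "this", "those", "that"),
  indefinite = c("all", "some", "many", "one"))

NOMINAL_OPENERS <- c(
  the = "definite", its = "possessive", their = "possessive",
  this = "demonstrative", these = "demonstrative", those = "demonstrative",
  that = "demonstrative", both = "distributive", such = "distributive",
  each = "distributive", either = "distributive", neither = "distributive",
  other = "indefinite", another = "indefinite", all = "indefinite")

DISREGARDED_PRONOUNS <- c("i", "me", "you", "your", "who")

sentence_token_table <- function(doc, sentence_index) {
  ph <- filter(doc$phrases, .data$sentence == sentence_index)
  bind_rows(map(seq_len(nrow(ph)), function(j) {
    tok <- ph$tokens[[j]]
    if (nrow(tok) == 0) return(NULL)
    mutate(tok, phrase_id = ph$id[j])
  }))
}

#' Is an occurrence of "it" pleonastic?
#'
#' Token-level patterns (with negation and modal verbs admitted as optional
#' arguments), matched within a 12-token window after "it":
#' 1. `IT [MODAL [NOT]?]? BE [NOT]? [ADJ|ADV|VP]* [THAT|WHETHER]`
#' 2. `IT [MODAL [NOT]?]? BE [NOT]? ADJ [FOR np]? TO VP`
#' 3. `IT [MODAL [NOT]?]? [SEEM|APPEAR|MEAN|FOLLOW] [THAT]?`
#'
#' @param tokens A tagged token tibble for the whole sentence.
#' @param it_position 1-based row index of the "it" token.
#' @param window Maximum number of tokens inspected after "it".
#' @return `TRUE` iff one of the patterns matches.
#' @export
#' @examples
#' tok <- pos_tag(tokenize_text("It is not known whether they interact"))
#' is_pleonastic_it(tok, 1)
is_pleonastic_it <- function(tokens, it_position, window = 12L) {
  n <- nrow(tokens)
  low <- str_to_lower(tokens$text)
  stopifnot(low[it_position] == "it")
  j <- it_position + 1L
  if (j > n) return(FALSE)
  if (tokens$pos[j] == "MODAL") {
    j <- j + 1L
    if (j <= n && low[j] == "not") j <- j + 1L
  }
  if (j > n) return(FALSE)
  if (low[j] %in% PLEONASTIC_VERBS) return(TRUE)           # pattern 3
  if (!low[j] %in% BE_FORMS) return(FALSE)
  j <- j + 1L
  if (j <= n && low[j] == "not") j <- j + 1L
  seen_adj <- FALSE
  limit <- min(n, it_position + window)
  while (j <= limit) {
    w <- low[j]
    tg <- tokens$pos[j]
    if (w %in% c("that", "whether")) return(TRUE)          # pattern 1
    if (w == "to" && seen_adj && j < n &&
        tokens$pos[j + 1] %in% c("VERB", "MODAL")) return(TRUE)  # pattern 2
    if (w == "for") {                                      # [FOR np]
      j <- j + 1L
      while (j <= limit && tokens$pos[j] %in% c("DET", "ADJ", "NOUN")) j <- j + 1L
      next
    }
    if (tg == "ADJ") { seen_adj <- TRUE; j <- j + 1L; next }
    if (tg %in% c("ADV", "VERB", "MODAL")) { j <- j + 1L; next }
    break
  }
  FALSE
}

#' Is a both/either/neither unit part of a correlative construction?
#'
#' Matches `[BOTH|EITHER|NEITHER] [NP|PP|UNK] [AND|OR|NOR] [NP|PP|UNK]` over
#' the chunk sequence. The nominal immediately governed by the unit may be
#' the remainder of the unit's own chunk ("both midazolam" chunked as one
#' NP) or the following chunk; correlative hits are removed from anaphor
#' candidacy.
#'
#' @param doc A `drug_document`.
#' @param phrase_id ID of the phrase containing the unit token.
#' @param unit_token 1-based index of the unit token inside that phrase.
#' @return `TRUE` iff the correlative pattern matches.
#' @export
is_correlative <- function(doc, phrase_id, unit_token = 1L) {
  i <- match(phrase_id, doc$phrases$id)
  if (is.na(i)) abort(sprintf("unknown phrase id '%s'", phrase_id))
  ph <- doc$phrases[i, ]
  tok <- ph$tokens[[1]]
  unit <- str_to_lower(tok$text[unit_token])
  if (!unit %in% c("both", "either", "neither")) return(FALSE)
  sent_ph <- filter(doc$phrases, .data$sentence == ph$sentence)
  k <- match(phrase_id, sent_ph$id)
  coordinable <- function(row) {
    row$type %in% c("NP", "PP", "UNK") &&
      any(grepl("[A-Za-z0-9]", row$tokens[[1]]$text))
  }
  # first nominal: remainder of the unit's own chunk, or the next chunk
  if (unit_token < nrow(tok)) {
    nxt <- k + 1L
  } else {
    if (k + 1L > nrow(sent_ph) || !coordinable(sent_ph[k + 1L, ])) return(FALSE)
    nxt <- k + 2L
  }
  if (nxt > nrow(sent_ph)) return(FALSE)
  conj <- sent_ph[nxt, ]
  if (conj$type != "CONJ" ||
      !str_to_lower(conj$text) %in% c("and", "or", "nor")) return(FALSE)
  if (nxt + 1L > nrow(sent_ph)) return(FALSE)
  coordinable(sent_ph[nxt + 1L, ])
}

#' Detect coordinative structures
#'
#' Maximal non-overlapping matches of
#' `([NP|PP|UNK] ,)* [NP|PP|UNK] [AND|OR|NOR] [NP|PP|UNK]` over each
#' sentence's chunk sequence (chained conjunctions, "X or Y and Z", join a
#' single group). Members are NP/PP/UNK chunks with lexical content; bare
#' pronoun chunks never coordinate. Downstream, a group is a single plural
#' center so that plural anaphors resolve to the whole list.
#'
#' @param doc A `drug_document`.
#' @return A tibble with columns `sentence`, `group_id` and `member_ids`
#'   (list-column of phrase IDs, in surface order).
#' @export
#' @examples
#' doc <- annotate_text("fluoxetine, sertraline and paroxetine inhibit P450 2D6.")
#' detect_coordinations(doc)$member_ids
detect_coordinations <- function(doc) {
  out <- list()
  for (si in doc$sentences$index) {
    ph <- filter(doc$phrases, .data$sentence == si)
    if (nrow(ph) < 3) next
    is_member <- map_lgl(seq_len(nrow(ph)), function(j) {
      tok <- ph$tokens[[j]]
      ph$type[j] %in% c("NP", "PP", "UNK") &&
        any(grepl("[A-Za-z0-9]", tok$text)) &&
        !(nrow(tok) == 1 && tok$pos[1] == "PRON")
    })
    sep_kind <- map_chr(seq_len(nrow(ph)), function(j) {
      txt <- str_to_lower(str_trim(ph$text[j]))
      if (ph$type[j] == "UNK" && txt == ",") "comma"
      else if (ph$type[j] == "CONJ" && txt %in% c("and", "or", "nor")) "conj"
      else "none"
    })
    j <- 1L
    while (j <= nrow(ph)) {
      if (!is_member[j]) { j <- j + 1L; next }
      members <- j
      k <- j
      n_conj <- 0L
      while (k + 2L <= nrow(ph) && sep_kind[k + 1L] != "none" && is_member[k + 2L]) {
        if (sep_kind[k + 1L] == "conj") n_conj <- n_conj + 1L
        members <- c(members, k + 2L)
        k <- k + 2L
      }
      if (length(members) >= 2 && n_conj >= 1) {
        out[[length(out) + 1]] <- tibble(
          sentence = si,
          group_id = sprintf("%s.c%d", doc$doc_id, length(out) + 1L),
          member_ids = list(ph$id[members]))
        j <- k + 1L
      } else {
        j <- j + 1L
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(sentence = integer(), group_id = character(),
                  member_ids = list()))
  }
  bind_rows(out)
}

that_is_relative <- function(doc, phrase_id) {
  # relative when immediately following an NP/PP and introducing a clause
  # that contains a verb; demonstrative otherwise
  ph <- doc$phrases
  i <- match(phrase_id, ph$id)
  sent_ph <- filter(ph, .data$sentence == ph$sentence[i])
  k <- match(phrase_id, sent_ph$id)
  prev_ok <- FALSE
  if (k > 1) {
    prev <- sent_ph[k - 1L, ]
    if (prev$type %in% c("NP", "PP")) prev_ok <- TRUE
    # allow an intervening comma chunk: "digoxin, that ..."
    if (!prev_ok && prev$type == "UNK" && str_trim(prev$text) == "," && k > 2 &&
        sent_ph$type[k - 2L] %in% c("NP", "PP")) prev_ok <- TRUE
  }
  if (!prev_ok) return(FALSE)
  if (k == nrow(sent_ph)) return(FALSE)
  later <- sent_ph[(k + 1L):nrow(sent_ph), ]
  any(map_lgl(later$tokens, function(t) any(t$pos %in% c("VERB", "MODAL"))))
}

#' Detect anaphoric expressions in a document
#'
#' Phase 1 of resolution. Pronominal candidates are the personal, reflexive,
#' relative, distributive, demonstrative and indefinite pronouns (first- and
#' second-person forms are disregarded), minus pleonastic-it and correlative
#' hits. Nominal candidates are NP/PP chunks opened by a definite article,
#' possessive, demonstrative, distributive or indefinite determiner whose
#' head is a drug-family noun or a generic drug term; possessive candidates
#' additionally require a qualitative-concept (`qlco`) head, and phrases
#' headed by a specific drug name (CUI-bearing) are disregarded. A bare
#' demonstrative chunk is a pronoun; determiner + noun is nominal. "that" is
#' relative after a nominal when a verb follows, demonstrative otherwise.
#'
#' @param doc A `drug_document` (preprocessed, e.g. via [annotate_text()]).
#' @param lexicon A `coref_lexicon` (specific-drug test).
#' @param terms Closed term lists, see [coref_terms()].
#' @return A tibble of mentions: `doc_id`, `phrase_id`, `sentence`, `pos`,
#'   `category` (pronominal/nominal), `subclass`, `unit` (the pronoun or
#'   opening determiner) and `number`.
#' @export
detect_anaphors <- function(doc, lexicon = default_lexicon(),
                            terms = coref_terms()) {
  ph <- doc$phrases
  rows <- list()
  sent_tok_cache <- list()
  sent_tokens <- function(si) {
    key <- as.character(si)
    if (is.null(sent_tok_cache[[key]])) {
      sent_tok_cache[[key]] <<- sentence_token_table(doc, si)
    }
    sent_tok_cache[[key]]
  }
  for (i in seq_len(nrow(ph))) {
    type <- ph$type[i]
    if (!type %in% c("NP", "PP")) next
    tok <- ph$tokens[[i]]
    if (nrow(tok) == 0) next
    # ---- pronominal: a bare pronoun chunk -------------------------------
    if (nrow(tok) == 1 && tok$pos[1] == "PRON") {
      w <- str_to_lower(tok$text[1])
      if (w %in% DISREGARDED_PRONOUNS) next
      subclass <- NULL
      if (w %in% PRONOMINAL_INVENTORY$personal) {
        if (w == "it") {
          st <- sent_tokens(ph$sentence[i])
          it_pos <- which(str_to_lower(st$text) == "it" & st$phrase_id == ph$id[i])[1]
          if (is_pleonastic_it(st, it_pos)) next
        }
        subclass <- "personal"
      } else if (w %in% PRONOMINAL_INVENTORY$reflexive) {
        subclass <- "reflexive"
      } else if (w == "which") {
        subclass <- "relative"
      } else if (w == "that") {
        subclass <- if (that_is_relative(doc, ph$id[i])) "relative" else "demonstrative"
      } else if (w %in% PRONOMINAL_INVENTORY$distributive) {
        if (is_correlative(doc, ph$id[i], 1L)) next
        subclass <- "distributive"
      } else if (w %in% c("these", "this", "those")) {
        subclass <- "demonstrative"
      } else if (w %in% PRONOMINAL_INVENTORY$indefinite) {
        subclass <- "indefinite"
      } else next
      num <- if (subclass == "relative") "unknown" else
        unname(PRONOUN_NUMBER[w]) %||% "unknown"
      rows[[length(rows) + 1]] <- tibble(
        doc_id = doc$doc_id, phrase_id = ph$id[i], sentence = ph$sentence[i],
        pos = ph$pos[i], category = "pronominal", subclass = subclass,
        unit = w, number = num)
      next
    }
    # ---- nominal: determiner-opened NP/PP with drug-denoting head -------
    first_content <- which(!tok$pos %in% c("PREP"))[1]
    if (is.na(first_content)) next
    opener <- str_to_lower(tok$text[first_content])
    if (!opener %in% names(NOMINAL_OPENERS)) next
    subclass <- unname(NOMINAL_OPENERS[opener])
    head_w <- str_to_lower(ph$head[i])
    if (ph$head_index[i] <= first_content) next  # no head after the opener
    # specific drug names are disregarded (CUI-based distinction)
    if (is_specific_drug_token(head_w, lexicon, terms)) next
    if (subclass == "possessive") {
      if (!"qlco" %in% ph$semtypes[[i]] &&
          !head_w %in% terms$qualitative_terms) next
    } else {
      if (!head_w %in% c(terms$generic_drug_terms, terms$family_nouns)) next
    }
    if (opener %in% c("both", "either", "neither") &&
        is_correlative(doc, ph$id[i], first_content)) next
    num <- if (subclass == "possessive") {
      if (opener == "its") "singular" else "plural"
    } else ph$number[i]
    rows[[length(rows) + 1]] <- tibble(
      doc_id = doc$doc_id, phrase_id = ph$id[i], sentence = ph$sentence[i],
      pos = ph$pos[i], category = "nominal", subclass = subclass,
      unit = opener, number = num)
  }
  if (length(rows) == 0) {
    return(tibble(doc_id = character(), phrase_id = character(),
                  sentence = integer(), pos = integer(), category = character(),
                  subclass = character(), unit = character(), number = character()))
  }
  bind_rows(rows)
}
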