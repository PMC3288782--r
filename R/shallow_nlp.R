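# Shallow linguistic analysis: sentence splitting, tokenization, coarse
# POS tagging from closed-class lists + suffix heuristics, chunking into
# NP/PP/VP/... phrases, concept attachment from the mini-lexicon, INN
# drug-family classification and grammatical number. This layer stands in
# for a full biomedical tagger: the downstream rules only need coarse tags
# and flat chunks.

ABBREVIATIONS <- c("e.g.", "i.e.", "etc.", "vs.", "dr.", "fig.", "approx.",
                   "b.i.d.", "t.i.d.", "q.d.", "p.o.", "i.v.")

MODAL_VERBS <- c("may", "might", "can", "could", "should", "would", "must",
                 "shall", "will", "do", "does", "did")
BE_FORMS <- c("is", "are", "was", "were", "be", "been", "being", "am")
PLEONASTIC_VERBS <- c("seem", "seems", "seemed", "appear", "appears",
                      "appeared", "mean", "means", "meant", "follow",
                      "follows", "followed")

PRONOUNS <- c("it", "they", "them", "itself", "themselves", "which", "who",
              "i", "me", "you", "he", "she", "we", "us")
# demonstratives / quantifier units that are DET before a nominal, PRON bare
DET_OR_PRON <- c("this", "that", "these", "those", "both", "each", "either",
                 "neither", "all", "some", "many", "one", "other", "another")
DETERMINERS <- c("the", "a", "an", "its", "their", "his", "her", "your",
                 "my", "our", "such", "no", "any", "every", "several", "few",
                 "certain", "similar", "more", "most", "much")
PREPOSITIONS <- c("of", "in", "with", "to", "for", "on", "by", "from", "at",
                  "during", "into", "after", "before", "between", "through",
                  "under", "over", "without", "via", "upon", "within",
                  "against", "among", "per", "than")
CONJUNCTIONS <- c("and", "or", "nor", "but", "while", "although", "because",
                  "if", "whether", "when", "since", "whereas", "though",
                  "unless", "so", "as", "however", "therefore", "thus",
                  "hence", "moreover", "furthermore")
VERB_STEMS <- c(
  "increase", "decrease", "inhibit", "induce", "reduce", "enhance",
  "potentiate", "alter", "affect", "modify", "prolong", "cause", "result",
  "require", "monitor", "avoid", "administer", "coadminister",
  "co-administer", "combine", "use", "take", "receive", "occur", "interact",
  "vary", "know", "recommend", "advise", "consider", "prescribe",
  "discontinue", "adjust", "observe", "report", "show", "suggest", "lead",
  "expect", "tolerate", "metabolize", "lower", "raise", "elevate",
  "diminish", "depress", "share", "titrate", "give", "warrant",
  "contraindicate", "undergo", "undergoes", "precede", "accompany",
  "exceed", "produce", "impair", "delay", "accelerate", "associate",
  "accumulate", "see")
ADVERBS <- c("not", "also", "well", "often", "only", "very", "too", "closely")
ADJECTIVES <- c(
  "additive", "pharmacological", "pharmacologic", "clinical", "adverse",
  "concomitant", "concurrent", "careful", "elderly", "possible",
  "impossible", "necessary", "unnecessary", "important", "likely",
  "unlikely", "advisable", "recommended", "known", "unknown", "adequate",
  "inadequate", "selective", "potent", "oral", "hepatic", "renal",
  "cardiac", "sedative", "anticoagulant", "antidepressant", "prolonged",
  "increased", "decreased", "reduced", "combined", "steady-state", "safe",
  "unsafe", "serotonin", "reuptake", "gradual", "abrupt", "complete",
  "advanced", "other", "several", "atrial", "progestational", "useful",
  "expected", "starting", "severe", "marked", "extensive", "excessive",
  "respiratory")

#' Tokenize text
#'
#' Splits on whitespace, detaches punctuation, and protects a small list of
#' abbreviations (`"e.g."`, `"i.e."`, ...) from the punctuation split.
#' Hyphenated words stay single tokens.
#'
#' @param text A single string (may be empty).
#' @return A token tibble (`text`, `pos = "OTHER"`, 0-based half-open
#'   `start`/`end` offsets into `text`).
#' @export
#' @examples
#' tokenize_text("they might increase dofetilide levels")
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) return(token_tibble(character()))
  out_text <- character()
  out_start <- integer()
  # locate whitespace-delimited words, then split punctuation inside each
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1) return(token_tibble(character()))
  for (k in seq_along(m)) {
    word <- substr(text, m[k], m[k] + attr(m, "match.length")[k] - 1)
    offset <- m[k] - 1L  # 0-based start of word
    if (str_to_lower(word) %in% ABBREVIATIONS) {
      out_text <- c(out_text, word)
      out_start <- c(out_start, offset)
      next
    }
    # trailing abbreviation + comma, e.g. "e.g.,"
    pieces <- regmatches(word, gregexpr("[A-Za-z0-9]+(?:[-'/.][A-Za-z0-9]+)*\\.?|[[:punct:]]", word))[[1]]
    # do not keep a trailing period attached unless the token is an abbreviation
    expanded <- list()
    for (p in pieces) {
      if (nchar(p) > 1 && endsWith(p, ".") && !str_to_lower(p) %in% ABBREVIATIONS) {
        expanded <- c(expanded, substr(p, 1, nchar(p) - 1), ".")
      } else {
        expanded <- c(expanded, p)
      }
    }
    pos_in_word <- 0L
    for (p in unlist(expanded)) {
      at <- regexpr(p, substr(word, pos_in_word + 1, nchar(word)), fixed = TRUE)
      start <- offset + pos_in_word + at - 1L
      out_text <- c(out_text, p)
      out_start <- c(out_start, start)
      pos_in_word <- pos_in_word + at - 1L + nchar(p)
    }
  }
  token_tibble(out_text, start = out_start, end = out_start + nchar(out_text))
}

#' Split text into sentences
#'
#' Period / question mark / exclamation mark followed by whitespace and an
#' uppercase letter ends a sentence; a small abbreviation guard list
#' (`"e.g."` etc.) blocks false splits.
#'
#' @param text A string.
#' @return Character vector of sentence strings (trimmed).
#' @export
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(str_trim(text))) return(character())
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  breaks <- integer()
  for (i in seq_len(n)) {
    if (!chars[i] %in% c(".", "?", "!")) next
    if (i == n) { breaks <- c(breaks, i); next }
    rest <- substr(text, i + 1, n)
    if (!grepl("^\\s+[A-Z\"(]", rest)) next
    # abbreviation guard: word ending at i
    before <- sub(".*\\s", "", substr(text, 1, i))
    if (str_to_lower(before) %in% ABBREVIATIONS) next
    if (grepl("^[A-Za-z]\\.$", before)) next  # single-initial
    breaks <- c(breaks, i)
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  out <- map_chr(seq_along(starts), function(k) {
    str_trim(substr(text, starts[k], ends[k]))
  })
  out[nzchar(out)]
}

is_punct_token <- function(x) grepl("^[[:punct:]]+$", x) & !grepl("[A-Za-z0-9]", x)

#' Assign coarse POS tags
#'
#' Closed-class word lists (pronouns, determiners, modals, prepositions,
#' conjunctions) plus suffix heuristics and lexicon membership for nouns.
#' Demonstratives and quantifier units ("this", "both", "all", ...) are
#' tagged `DET` when a nominal follows and `PRON` when bare; "as" is `CONJ`
#' before a pronoun/determiner and `PREP` otherwise.
#'
#' @param tokens A token tibble from [tokenize_text()].
#' @param lexicon A `coref_lexicon` used to force `NOUN` on known concepts.
#' @return The token tibble with the `pos` column filled in.
#' @export
pos_tag <- function(tokens, lexicon = default_lexicon()) {
  n <- nrow(tokens)
  if (n == 0) return(tokens)
  low <- str_to_lower(tokens$text)
  tags <- character(n)
  nounish_ahead <- function(i) {
    # TRUE if token i+1 plausibly begins a nominal rest (ADJ/NOUN)
    if (i >= n) return(FALSE)
    w <- low[i + 1]
    if (is_punct_token(w)) return(FALSE)
    if (w %in% DETERMINERS) return(TRUE)  # determiner chain: "all such agents"
    if (w %in% c(PRONOUNS, MODAL_VERBS, BE_FORMS, PREPOSITIONS,
                 CONJUNCTIONS, DET_OR_PRON, ADVERBS)) return(FALSE)
    if (inflected_verb(w)) return(FALSE)
    TRUE
  }
  irregular <- c("seen", "taken", "given", "shown", "made", "found", "kept",
                 "held", "done", "gone", "seeing")
  inflected_verb <- function(w) {
    if (w %in% irregular) return(TRUE)
    cand <- unique(c(w, sub("s$", "", w), sub("es$", "", w), sub("ed$", "", w),
                     sub("d$", "", w), sub("ing$", "", w),
                     paste0(sub("ing$", "e", w)), paste0(sub("ed$", "e", w))))
    any(cand %in% VERB_STEMS)
  }
  in_lex <- !is.na(match(low, lexicon$surface))
  lex_types <- map(match(low, lexicon$surface), function(i) {
    if (is.na(i)) character() else lexicon$semtypes[[i]]
  })
  for (i in seq_len(n)) {
    w <- low[i]
    tags[i] <- if (is_punct_token(w)) "PUNCT"
    else if (in_lex[i]) "NOUN"
    else if (w %in% BE_FORMS) "VERB"
    else if (w %in% MODAL_VERBS) "MODAL"
    else if (w %in% c("not", "n't")) "ADV"
    else if (w %in% DETERMINERS) "DET"
    else if (w %in% DET_OR_PRON) { if (nounish_ahead(i)) "DET" else "PRON" }
    else if (w %in% PRONOUNS) "PRON"
    else if (w == "as") { if (i < n && low[i + 1] %in% c(PRONOUNS, DET_OR_PRON, DETERMINERS)) "CONJ" else "PREP" }
    else if (w %in% PREPOSITIONS) "PREP"
    else if (w %in% CONJUNCTIONS) "CONJ"
    else if (w %in% ADJECTIVES) "ADJ"
    else if (w %in% ADVERBS || grepl("ly$", w)) "ADV"
    else if (w %in% PLEONASTIC_VERBS || inflected_verb(w)) "VERB"
    else if (grepl("(al|ic|ive|ous|able|ible)$", w) && nchar(w) > 4) "ADJ"
    else "NOUN"
  }
  # 'other'/'another'/'one' are DET in ADJECTIVES overlap; DET_OR_PRON wins above
  tokens$pos <- tags
  tokens
}

is_specific_drug_token <- function(w, lexicon, terms) {
  i <- match(str_to_lower(w), lexicon$surface)
  !is.na(i) && !is.na(lexicon$cui[i]) &&
    length(intersect(lexicon$semtypes[[i]], terms$drug_semtypes)) > 0
}

#' Chunk a tagged token sequence into phrases
#'
#' Greedy left-to-right chunking: `PP` = preposition + nominal rest, `NP` =
#' optional determiner/possessive + modifiers + head noun(s), `VP` = modal /
#' verb / adverb runs (including infinitival "to"), bare pronouns form their
#' own `NP`, conjunctions their own `CONJ` chunk and punctuation an `UNK`
#' chunk. A known specific drug name starts a fresh nominal unless it is
#' preceded by a determiner, adjective or preposition inside the open chunk,
#' so "In addition triamterene" splits into a PP and a drug NP. The head of
#' an NP/PP is its rightmost noun.
#'
#' @param tokens A tagged token tibble ([pos_tag()]).
#' @param lexicon A `coref_lexicon` (drug-boundary heuristic).
#' @return A tibble with columns `type`, `tokens` (list-column of token
#'   tibbles) and `head_index`; every input token lands in exactly one
#'   chunk.
#' @export
chunk_tokens <- function(tokens, lexicon = default_lexicon()) {
  n <- nrow(tokens)
  out <- list()
  terms <- coref_terms()
  push <- function(type, idx) {
    tok <- tokens[idx, , drop = FALSE]
    hi <- if (type %in% c("NP", "PP")) {
      nn <- which(tok$pos %in% c("NOUN", "PRON"))
      if (length(nn) > 0) max(nn) else nrow(tok)
    } else nrow(tok)
    out[[length(out) + 1]] <<- tibble(type = type, tokens = list(tok),
                                      head_index = as.integer(hi))
  }
  i <- 1L
  low <- str_to_lower(tokens$text)
  while (i <= n) {
    tag <- tokens$pos[i]
    if (tag == "PUNCT") { push("UNK", i); i <- i + 1L; next }
    if (tag == "CONJ") { push("CONJ", i); i <- i + 1L; next }
    if (tag == "PREP" || tag == "DET" || tag == "ADJ" || tag == "NOUN") {
      is_pp <- tag == "PREP"
      j <- i
      if (is_pp) {
        # infinitival / pre-verbal "to": goes with the verb phrase
        if (low[i] == "to" && i < n && tokens$pos[i + 1] %in% c("VERB", "MODAL")) {
          k <- i + 1L
          while (k <= n && tokens$pos[k] %in% c("VERB", "MODAL", "ADV")) k <- k + 1L
          push("VP", i:(k - 1L)); i <- k; next
        }
        j <- j + 1L
        if (j > n || !tokens$pos[j] %in% c("DET", "ADJ", "NOUN", "PRON")) {
          push("UNK", i); i <- i + 1L; next
        }
        if (tokens$pos[j] == "PRON") { push("PP", i:j); i <- j + 1L; next }
      }
      # nominal rest: optional DET(s), then ADJ/NOUN run with drug boundary
      k <- j
      if (k <= n && tokens$pos[k] == "DET") {
        k <- k + 1L
        while (k <= n && tokens$pos[k] == "DET") k <- k + 1L  # "all such"
      }
      seen_noun <- FALSE
      while (k <= n && tokens$pos[k] %in% c("ADJ", "NOUN")) {
        if (tokens$pos[k] == "NOUN" && seen_noun &&
            is_specific_drug_token(low[k], lexicon, terms) &&
            !is_specific_drug_token(low[k - 1], lexicon, terms)) {
          break  # a drug name opens a new nominal after a plain noun
        }
        if (tokens$pos[k] == "NOUN") seen_noun <- TRUE
        k <- k + 1L
      }
      if (k == i) { push("UNK", i); i <- i + 1L; next }
      span <- i:(k - 1L)
      has_content <- any(tokens$pos[span] %in% c("NOUN", "ADJ", "DET", "PRON"))
      push(if (is_pp) "PP" else if (has_content && any(tokens$pos[span] %in% c("NOUN"))) "NP"
           else if (all(tokens$pos[span] == "ADJ")) "ADJP" else "NP", span)
      i <- k
      next
    }
    if (tag == "PRON") { push("NP", i); i <- i + 1L; next }
    if (tag %in% c("MODAL", "VERB")) {
      k <- i
      while (k <= n && (tokens$pos[k] %in% c("MODAL", "VERB", "ADV") ||
                        (low[k] == "to" && k < n && tokens$pos[k + 1] == "VERB"))) {
        k <- k + 1L
      }
      push("VP", i:(k - 1L)); i <- k; next
    }
    if (tag == "ADV") { push("ADVP", i); i <- i + 1L; next }
    push("UNK", i); i <- i + 1L
  }
  if (length(out) == 0) {
    return(tibble(type = character(), tokens = list(), head_index = integer()))
  }
  bind_rows(out)
}

#' Attach lexicon concepts to a phrase row
#'
#' Tries the longest contiguous token sub-span first (excluding leading
#' prepositions and determiners), then shorter spans, and populates the
#' CUI, concept name and semantic types of the first lexicon match.
#' Qualitative-concept heads ("effects", "properties", ...) pick up the
#' `qlco` type through their lexicon entries.
#'
#' @param phrase A one-row phrase tibble ([phrase_row()]).
#' @param lexicon A `coref_lexicon`.
#' @return The phrase row with `cui`, `concept`, `semtypes` filled when a
#'   match exists, otherwise unchanged.
#' @export
attach_semantics <- function(phrase, lexicon = default_lexicon()) {
  tok <- phrase$tokens[[1]]
  if (nrow(tok) == 0) return(phrase)
  content <- which(!tok$pos %in% c("PREP", "DET", "PUNCT"))
  if (length(content) == 0) return(phrase)
  spans <- list()
  for (len in rev(seq_along(content))) {
    for (s in seq_len(length(content) - len + 1)) {
      idx <- content[s:(s + len - 1)]
      if (all(diff(idx) == 1)) spans <- c(spans, list(idx))
    }
  }
  for (idx in spans) {
    key <- str_to_lower(paste(tok$text[idx], collapse = " "))
    m <- match(key, lexicon$surface)
    if (!is.na(m)) {
      phrase$cui <- lexicon$cui[m]
      phrase$concept <- lexicon$concept[m]
      phrase$semtypes <- list(lexicon$semtypes[[m]])
      return(phrase)
    }
  }
  phrase
}

#' Determine grammatical number of a head word
#'
#' Lexical patterns over the uppercased head: plural iff it matches
#' `[A-Z]+(S|IES|OES|XES|SHES|CHES|SES|ZES)` and does not match the
#' singular exception `[A-Z]+(U|S)S` (so "BOLUS" and "FLUVOXAMINE" are
#' singular, "INHIBITORS" plural).
#'
#' @param head Character vector of head words.
#' @return `"singular"` or `"plural"` per element (total and
#'   deterministic; non-alphabetic heads are singular).
#' @export
#' @examples
#' grammatical_number(c("INHIBITORS", "FLUVOXAMINE", "BOLUS"))
grammatical_number <- function(head) {
  h <- str_to_upper(head)
  plural <- grepl("^[A-Z]+(S|IES|OES|XES|SHES|CHES|SES|ZES)$", h)
  singular_exc <- grepl("^[A-Z]+(U|S)S$", h)
  ifelse(plural & !singular_exc, "plural", "singular")
}

PRONOUN_NUMBER <- c(
  it = "singular", itself = "singular", this = "singular", that = "singular",
  each = "singular", either = "singular", neither = "singular",
  one = "singular", another = "singular",
  they = "plural", them = "plural", themselves = "plural", these = "plural",
  those = "plural", both = "plural", all = "plural", some = "plural",
  many = "plural", other = "plural",
  which = "unknown", who = "unknown")

phrase_number <- function(type, tok, head_index) {
  if (!type %in% c("NP", "PP") || nrow(tok) == 0) return("unknown")
  head <- tok$text[head_index]
  if (tok$pos[head_index] == "PRON") {
    return(unname(PRONOUN_NUMBER[str_to_lower(head)]) %||% "unknown")
  }
  if (!grepl("^[A-Za-z-]+$", head)) return("unknown")
  grammatical_number(head)
}

#' Run the full shallow-annotation pipeline on plain text
#'
#' Splits sentences, tokenizes, tags, chunks, attaches lexicon concepts,
#' classifies drug families by INN affix and determines grammatical number,
#' producing a validated [drug_document()]. Phrase IDs are `s{i}.p{j}` with
#' a document-global running phrase counter. A phrase recognised as a drug
#' only through its INN affix (no lexicon concept) is assigned semantic
#' type `phsu` so that it still participates in semantic agreement.
#'
#' @param text Plain text of the passage.
#' @param doc_id Document identifier.
#' @param lexicon A `coref_lexicon`.
#' @param affixes An `inn_affix_table`.
#' @return A `drug_document`.
#' @export
#' @examples
#' doc <- annotate_text(
#'   "In addition triamterene, metformin and amiloride should be
#'    co-administered with care as they might increase dofetilide levels.")
#' phrases_in_order(doc)[, c("id", "type", "text", "number")]
annotate_text <- function(text, doc_id = "doc", lexicon = default_lexicon(),
                          affixes = default_affix_table()) {
  sents <- split_sentences(text)
  sent_tbl <- tibble(index = seq_along(sents) - 1L, text = sents)
  counter <- 0L
  terms <- coref_terms()
  phr <- bind_rows(map(seq_along(sents), function(i) {
    tok <- pos_tag(tokenize_text(sents[i]), lexicon)
    ch <- chunk_tokens(tok, lexicon)
    if (nrow(ch) == 0) return(NULL)
    bind_rows(map(seq_len(nrow(ch)), function(j) {
      counter <<- counter + 1L
      t_j <- ch$tokens[[j]]
      pr <- phrase_row(
        id = sprintf("s%d.p%d", i - 1L, counter),
        sentence = i - 1L, pos = j - 1L, type = ch$type[j],
        tokens = t_j, head_index = ch$head_index[j])
      pr <- attach_semantics(pr, lexicon)
      head_word <- pr$head
      fam <- NA_character_
      if (pr$type %in% c("NP", "PP")) {
        # classify the drug surface: the lexicon concept if any, else the head
        drug_surface <- if (!is.na(pr$cui)) pr$concept else head_word
        fam <- classify_inn_affix(drug_surface, affixes)
        if (is.na(fam)) fam <- classify_inn_affix(head_word, affixes)
        if (!is.na(fam) && length(pr$semtypes[[1]]) == 0) {
          pr$semtypes <- list("phsu")  # INN-recognised drug, no lexicon entry
        }
      }
      pr$drug_family <- fam
      pr$number <- phrase_number(pr$type, t_j, pr$head_index)
      pr
    }))
  }))
  if (is.null(phr) || nrow(phr) == 0) phr <- phrase_row("x", 0L, 0L, "NP", "x")[0, ]
  drug_document(doc_id, sent_tbl, phr, source = "annotate_text")
}
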