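# Document model: sentences of chunked phrases with stable IDs, gold
# anaphora annotations, validation, and the JSON / XML interchange dialects.

PHRASE_TYPES <- c("NP", "PP", "VP", "ADJP", "ADVP", "CONJ", "UNK")
POS_TAGS <- c("NOUN", "VERB", "MODAL", "ADJ", "ADV", "DET", "PRON",
              "PREP", "CONJ", "PUNCT", "OTHER")

#' Construct a drug-interaction document
#'
#' The central container: an ordered list of sentences, each an ordered list
#' of chunked phrases. Phrase IDs follow the `s{i}.p{j}` scheme (sentence
#' index, document-global phrase counter) for documents produced by
#' [annotate_text()]; hand-encoded or imported documents keep their IDs
#' verbatim, and only uniqueness plus surface order of the phrase rows is
#' enforced.
#'
#' @param doc_id Document identifier string.
#' @param sentences Tibble with columns `index` (0-based, contiguous) and
#'   `text`.
#' @param phrases Tibble with columns `id`, `sentence` (0-based index),
#'   `pos` (0-based position within the sentence), `type` (one of NP, PP,
#'   VP, ADJP, ADVP, CONJ, UNK), `text`, `tokens` (list-column of tibbles
#'   with `text`, `pos`, `start`, `end`), `head_index` (1-based index into
#'   `tokens`), `head`, `cui`, `concept`, `semtypes` (list-column),
#'   `drug_family`, `number` (singular/plural/unknown). Rows must be in
#'   surface order.
#' @param gold Optional gold anaphora annotations: tibble with `anaphor_id`,
#'   `antecedent_ids` (list-column of character vectors), `category`
#'   (pronominal/nominal) and `subclass`.
#' @param source Free-text provenance.
#' @return An object of class `drug_document`.
#' @export
drug_document <- function(doc_id, sentences, phrases, gold = empty_gold(),
                          source = "") {
  doc <- structure(
    list(doc_id = doc_id,
         sentences = tibble::as_tibble(sentences),
         phrases = tibble::as_tibble(phrases),
         gold = tibble::as_tibble(gold),
         source = source),
    class = "drug_document")
  validate_document(doc)
  doc
}

#' @export
print.drug_document <- function(x, ...) {
  cat(sprintf("<drug_document '%s': %d sentence(s), %d phrase(s), %d gold link(s)>\n",
              x$doc_id, nrow(x$sentences), nrow(x$phrases), nrow(x$gold)))
  invisible(x)
}

#' An empty gold-annotation table
#' @return A zero-row gold tibble with the canonical columns.
#' @export
empty_gold <- function() {
  tibble(anaphor_id = character(), antecedent_ids = list(),
         category = character(), subclass = character())
}

#' Validate a drug_document
#'
#' Checks the structural invariants: contiguous 0-based sentence indices,
#' unique phrase IDs, phrases attached to existing sentences and listed in
#' surface order, valid head indices, and gold annotations whose IDs exist
#' and whose antecedents precede the anaphor in document order.
#'
#' @param doc A `drug_document`.
#' @return `doc`, invisibly; aborts with an informative message on the
#'   first violated invariant.
#' @export
validate_document <- function(doc) {
  s <- doc$sentences
  p <- doc$phrases
  if (nrow(s) > 0 && !identical(as.integer(s$index), seq_len(nrow(s)) - 1L)) {
    abort(sprintf("document '%s': sentence indices must be 0..%d contiguous",
                  doc$doc_id, nrow(s) - 1L))
  }
  if (nrow(p) == 0) return(invisible(doc))
  dup <- p$id[duplicated(p$id)]
  if (length(dup) > 0) {
    abort(sprintf("document '%s': duplicate phrase id '%s'", doc$doc_id, dup[1]))
  }
  bad_sent <- setdiff(unique(p$sentence), s$index)
  if (length(bad_sent) > 0) {
    abort(sprintf("document '%s': phrase refers to missing sentence %d",
                  doc$doc_id, bad_sent[1]))
  }
  if (is.unsorted(p$sentence)) {
    abort(sprintf("document '%s': phrases not grouped in sentence order", doc$doc_id))
  }
  for (si in unique(p$sentence)) {
    pos <- p$pos[p$sentence == si]
    if (any(diff(pos) <= 0)) {
      abort(sprintf("document '%s': phrase positions not increasing in sentence %d",
                    doc$doc_id, si))
    }
  }
  bad_type <- setdiff(unique(p$type), PHRASE_TYPES)
  if (length(bad_type) > 0) {
    abort(sprintf("document '%s': unknown phrase type '%s'", doc$doc_id, bad_type[1]))
  }
  ok_head <- map2(p$tokens, p$head_index, function(tok, h) {
    nrow(tok) == 0 || (h >= 1 && h <= nrow(tok))
  })
  if (!all(unlist(ok_head))) {
    abort(sprintf("document '%s': head_index out of range for phrase '%s'",
                  doc$doc_id, p$id[which(!unlist(ok_head))[1]]))
  }
  validate_gold(doc$gold, doc)
  invisible(doc)
}

validate_gold <- function(gold, doc) {
  if (nrow(gold) == 0) return(invisible(gold))
  rank <- stats::setNames(seq_len(nrow(doc$phrases)), doc$phrases$id)
  for (i in seq_len(nrow(gold))) {
    ana <- gold$anaphor_id[i]
    ants <- gold$antecedent_ids[[i]]
    if (!ana %in% names(rank)) {
      abort(sprintf("gold annotation refers to unknown anaphor '%s'", ana))
    }
    if (length(ants) == 0) {
      abort(sprintf("gold annotation for '%s' has no antecedents", ana))
    }
    missing <- setdiff(ants, names(rank))
    if (length(missing) > 0) {
      abort(sprintf("gold annotation refers to unknown antecedent '%s'", missing[1]))
    }
    if (any(rank[ants] >= rank[ana])) {
      abort(sprintf(
        "gold annotation for '%s': antecedent '%s' does not precede the anaphor",
        ana, ants[which(rank[ants] >= rank[ana])[1]]))
    }
  }
  invisible(gold)
}

#' All phrases of a document in global document order
#'
#' @param doc A `drug_document`.
#' @return The phrase tibble ordered by sentence index, then position
#'   within the sentence (stable).
#' @export
phrases_in_order <- function(doc) {
  arrange(doc$phrases, .data$sentence, .data$pos)
}

# ---- construction helpers -------------------------------------------------

#' Build a token table
#'
#' @param text Character vector of token strings.
#' @param pos Coarse POS tags (defaults to `OTHER`).
#' @param start,end 0-based half-open character offsets (computed by spacing
#'   tokens one apart when omitted).
#' @return A token tibble with columns `text`, `pos`, `start`, `end`.
#' @export
token_tibble <- function(text, pos = rep("OTHER", length(text)),
                         start = NULL, end = NULL) {
  if (is.null(start)) {
    widths <- nchar(text)
    start <- cumsum(c(0L, head(widths, -1) + 1L))
    end <- start + widths
  }
  tibble(text = text, pos = pos, start = as.integer(start), end = as.integer(end))
}

#' Build a single phrase row
#'
#' Convenience constructor for hand-built documents (fixtures, tests).
#'
#' @param id Phrase ID.
#' @param sentence 0-based sentence index.
#' @param pos 0-based position within the sentence.
#' @param type Phrase type (NP, PP, ...).
#' @param tokens A token tibble (see [token_tibble()]); a plain character
#'   vector is converted with default tags.
#' @param head_index 1-based head token index (defaults to the last token).
#' @param cui,concept,drug_family Optional concept fields.
#' @param semtypes Character vector of semantic type abbreviations.
#' @param number Grammatical number: singular, plural or unknown.
#' @return A one-row phrase tibble.
#' @export
phrase_row <- function(id, sentence, pos, type, tokens,
                       head_index = NULL, cui = NA_character_,
                       concept = NA_character_, semtypes = character(),
                       drug_family = NA_character_, number = "unknown") {
  if (is.character(tokens)) tokens <- token_tibble(tokens)
  if (is.null(head_index)) head_index <- max(1L, nrow(tokens))
  head_word <- if (nrow(tokens) > 0) tokens$text[head_index] else ""
  tibble(
    id = id, sentence = as.integer(sentence), pos = as.integer(pos),
    type = type, text = paste(tokens$text, collapse = " "),
    tokens = list(tokens), head_index = as.integer(head_index),
    head = head_word,
    cui = cui, concept = concept, semtypes = list(semtypes),
    drug_family = drug_family, number = number)
}

# ---- JSON dialect ---------------------------------------------------------

doc_to_list <- function(doc, links = NULL) {
  sent_list <- map(seq_len(nrow(doc$sentences)), function(i) {
    si <- doc$sentences$index[i]
    ph <- filter(doc$phrases, .data$sentence == si)
    list(
      index = si,
      text = doc$sentences$text[i],
      phrases = map(seq_len(nrow(ph)), function(j) {
        tok <- ph$tokens[[j]]
        list(
          id = ph$id[j], type = ph$type[j], text = ph$text[j],
          tokens = map(seq_len(nrow(tok)), function(k) {
            list(text = tok$text[k], pos = tok$pos[k],
                 span = c(tok$start[k], tok$end[k]))
          }),
          head = ph$head_index[j] - 1L,  # 0-based on disk
          cui = ph$cui[j], concept = ph$concept[j],
          semtypes = as.list(ph$semtypes[[j]]),
          drug_family = ph$drug_family[j], number = ph$number[j])
      }))
  })
  out <- list(doc_id = doc$doc_id, source = doc$source, sentences = sent_list,
              gold = map(seq_len(nrow(doc$gold)), function(i) {
                list(anaphor = doc$gold$anaphor_id[i],
                     antecedents = as.list(doc$gold$antecedent_ids[[i]]),
                     class = paste(doc$gold$category[i], doc$gold$subclass[i],
                                   sep = "_"))
              }))
  if (!is.null(links) && nrow(links) > 0) {
    out$links <- map(seq_len(nrow(links)), function(i) {
      list(anaphor = links$anaphor_id[i],
           antecedents = as.list(links$antecedent_ids[[i]]),
           strategy = links$strategy[i], resolved = links$resolved[i])
    })
  }
  out
}

scalar_or <- function(x, default) {
  if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x))) default else x
}

doc_from_list <- function(lst) {
  for (field in c("doc_id", "sentences")) {
    if (is.null(lst[[field]])) abort(sprintf("malformed document: missing '%s'", field))
  }
  sents <- tibble(
    index = map_int(lst$sentences, function(s) {
      if (is.null(s$index)) abort("malformed sentence: missing 'index'")
      as.integer(s$index)
    }),
    text = map_chr(lst$sentences, function(s) scalar_or(s$text, "")))
  phr <- bind_rows(map(lst$sentences, function(s) {
    ph <- s$phrases
    if (is.null(ph) || length(ph) == 0) return(NULL)
    bind_rows(imap(ph, function(p, j) {
      if (is.null(p$id)) abort("malformed phrase: missing 'id'")
      toks <- p$tokens
      tok <- if (is.null(toks) || length(toks) == 0) {
        token_tibble(character())
      } else {
        tibble(
          text = map_chr(toks, function(t) scalar_or(t$text, "")),
          pos = map_chr(toks, function(t) scalar_or(t$pos, "OTHER")),
          start = map_int(toks, function(t) as.integer(t$span[[1]])),
          end = map_int(toks, function(t) as.integer(t$span[[2]])))
      }
      phrase_row(
        id = p$id, sentence = as.integer(s$index), pos = j - 1L,
        type = scalar_or(p$type, "UNK"), tokens = tok,
        head_index = as.integer(scalar_or(p$head, nrow(tok) - 1L)) + 1L,
        cui = scalar_or(p$cui, NA_character_),
        concept = scalar_or(p$concept, NA_character_),
        semtypes = as.character(unlist(p$semtypes)),
        drug_family = scalar_or(p$drug_family, NA_character_),
        number = scalar_or(p$number, "unknown"))
    }))
  }))
  if (is.null(phr) || nrow(phr) == 0) {
    phr <- phrase_row("x", 0L, 0L, "NP", "x")[0, ]
  }
  gold <- if (is.null(lst$gold) || length(lst$gold) == 0) empty_gold() else {
    bind_rows(map(lst$gold, function(g) {
      cls <- str_split(scalar_or(g$class, "pronominal_personal"), "_", n = 2)[[1]]
      tibble(anaphor_id = g$anaphor,
             antecedent_ids = list(as.character(unlist(g$antecedents))),
             category = cls[1], subclass = cls[2])
    }))
  }
  drug_document(lst$doc_id, sents, phr, gold,
                source = scalar_or(lst$source, ""))
}

#' Read a document from JSON or XML
#'
#' Phrase IDs are preserved verbatim. The file is validated on read:
#' malformed records raise a schema error naming the offending element,
#' duplicate phrase IDs or gold antecedents that do not precede their
#' anaphor raise an integrity error.
#'
#' @param path Path to the file.
#' @param format `"json"` (canonical) or `"xml"` (the per-phrase attribute
#'   dialect with `ID-ANTECEDENT` on annotated anaphor phrases).
#' @return A `drug_document`.
#' @export
read_document <- function(path, format = c("json", "xml")) {
  format <- match.arg(format)
  if (format == "json") {
    doc_from_list(jsonlite::read_json(path))
  } else {
    doc_from_xml(xml2::read_xml(path))
  }
}

#' Write a document to JSON or XML
#'
#' Round-trip safe: `read_document()` on the written file reproduces the
#' document field for field. Resolution links, when supplied, are stored
#' alongside the document (JSON `links` array; `SYS-ANTECEDENT` /
#' `SYS-STRATEGY` attributes in XML) without disturbing the gold
#' `ID-ANTECEDENT` annotation.
#'
#' @param doc A `drug_document`.
#' @param path Output file path.
#' @param links Optional resolution-link tibble (from [resolve_anaphora()]);
#'   links referencing unknown phrase IDs raise an integrity error.
#' @param format `"json"` or `"xml"`.
#' @return `path`, invisibly.
#' @export
write_document <- function(doc, path, links = NULL, format = c("json", "xml")) {
  format <- match.arg(format)
  validate_document(doc)
  if (!is.null(links) && nrow(links) > 0) {
    ids <- doc$phrases$id
    bad <- setdiff(c(links$anaphor_id, unlist(links$antecedent_ids)), ids)
    if (length(bad) > 0) {
      abort(sprintf("link refers to unknown phrase id '%s'", bad[1]))
    }
  }
  if (format == "json") {
    jsonlite::write_json(doc_to_list(doc, links), path, auto_unbox = TRUE,
                         null = "null", digits = NA, pretty = TRUE)
  } else {
    xml2::write_xml(doc_to_xml(doc, links), path)
  }
  invisible(path)
}

# ---- XML dialect ----------------------------------------------------------

doc_to_xml <- function(doc, links = NULL) {
  root <- xml2::xml_new_root("document", id = doc$doc_id, source = doc$source)
  gold_by_ana <- stats::setNames(
    seq_len(nrow(doc$gold)), doc$gold$anaphor_id)
  link_by_ana <- if (!is.null(links) && nrow(links) > 0) {
    stats::setNames(seq_len(nrow(links)), links$anaphor_id)
  } else integer()
  for (i in seq_len(nrow(doc$sentences))) {
    si <- doc$sentences$index[i]
    sn <- xml2::xml_add_child(root, "sentence", index = as.character(si),
                              text = doc$sentences$text[i])
    ph <- filter(doc$phrases, .data$sentence == si)
    for (j in seq_len(nrow(ph))) {
      attrs <- list(ID = ph$id[j], TYPE = ph$type[j],
                    HEAD = as.character(ph$head_index[j] - 1L),
                    NUMBER = ph$number[j])
      if (!is.na(ph$cui[j])) attrs$CUI <- ph$cui[j]
      if (!is.na(ph$concept[j])) attrs$CONCEPT <- ph$concept[j]
      if (length(ph$semtypes[[j]]) > 0) {
        attrs$SEMTYPES <- paste(ph$semtypes[[j]], collapse = ",")
      }
      if (!is.na(ph$drug_family[j])) attrs$`DRUG-FAMILY` <- ph$drug_family[j]
      gi <- gold_by_ana[ph$id[j]]
      if (!is.na(gi)) {
        attrs$`ID-ANTECEDENT` <- paste(doc$gold$antecedent_ids[[gi]], collapse = ",")
        attrs$`ANAPHOR-CLASS` <- paste(doc$gold$category[gi],
                                       doc$gold$subclass[gi], sep = "_")
      }
      li <- link_by_ana[ph$id[j]]
      if (length(li) == 1 && !is.na(li) && isTRUE(links$resolved[li])) {
        attrs$`SYS-ANTECEDENT` <- paste(links$antecedent_ids[[li]], collapse = ",")
        attrs$`SYS-STRATEGY` <- links$strategy[li]
      }
      pn <- do.call(xml2::xml_add_child, c(list(sn, "phrase"), attrs))
      tok <- ph$tokens[[j]]
      for (k in seq_len(nrow(tok))) {
        tn <- xml2::xml_add_child(pn, "token", pos = tok$pos[k],
                                  start = as.character(tok$start[k]),
                                  end = as.character(tok$end[k]))
        xml2::xml_text(tn) <- tok$text[k]
      }
    }
  }
  root
}

doc_from_xml <- function(root) {
  sents_nodes <- xml2::xml_find_all(root, "./sentence")
  sents <- tibble(
    index = map_int(sents_nodes, function(s) as.integer(xml2::xml_attr(s, "index"))),
    text = map_chr(sents_nodes, function(s) xml2::xml_attr(s, "text") %||% ""))
  gold_rows <- list()
  phr <- bind_rows(map(sents_nodes, function(s) {
    si <- as.integer(xml2::xml_attr(s, "index"))
    ph_nodes <- xml2::xml_find_all(s, "./phrase")
    bind_rows(imap(ph_nodes, function(p, j) {
      id <- xml2::xml_attr(p, "ID")
      if (is.na(id)) abort("malformed phrase element: missing ID attribute")
      tok_nodes <- xml2::xml_find_all(p, "./token")
      tok <- if (length(tok_nodes) == 0) token_tibble(character()) else tibble(
        text = xml2::xml_text(tok_nodes),
        pos = xml2::xml_attr(tok_nodes, "pos"),
        start = as.integer(xml2::xml_attr(tok_nodes, "start")),
        end = as.integer(xml2::xml_attr(tok_nodes, "end")))
      ants <- xml2::xml_attr(p, "ID-ANTECEDENT")
      if (!is.na(ants)) {
        cls <- str_split(xml2::xml_attr(p, "ANAPHOR-CLASS") %||%
                           "pronominal_personal", "_", n = 2)[[1]]
        gold_rows[[length(gold_rows) + 1]] <<- tibble(
          anaphor_id = id,
          antecedent_ids = list(str_split(ants, ",")[[1]]),
          category = cls[1], subclass = cls[2])
      }
      st <- xml2::xml_attr(p, "SEMTYPES")
      phrase_row(
        id = id, sentence = si, pos = j - 1L,
        type = xml2::xml_attr(p, "TYPE") %||% "UNK", tokens = tok,
        head_index = as.integer(xml2::xml_attr(p, "HEAD")) + 1L,
        cui = xml2::xml_attr(p, "CUI"),
        concept = xml2::xml_attr(p, "CONCEPT"),
        semtypes = if (is.na(st)) character() else str_split(st, ",")[[1]],
        drug_family = xml2::xml_attr(p, "DRUG-FAMILY"),
        number = xml2::xml_attr(p, "NUMBER") %||% "unknown")
    }))
  }))
  if (is.null(phr) || nrow(phr) == 0) phr <- phrase_row("x", 0L, 0L, "NP", "x")[0, ]
  gold <- if (length(gold_rows) == 0) empty_gold() else bind_rows(gold_rows)
  drug_document(xml2::xml_attr(root, "id"), sents, phr, gold,
                source = xml2::xml_attr(root, "source") %||% "")
}
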