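# Phases 2-3: determination of anaphora scope and antecedent selection.
# Centering search over the current + previous sentence, a local
# closest-match strategy for relative / reflexive / possessive anaphors,
# and the closest-nominal-phrase baseline.

features_for_phrases <- function(doc, ids, lexicon, terms) {
  ph <- doc$phrases[match(ids, doc$phrases$id), , drop = FALSE]
  spec <- map_lgl(seq_len(nrow(ph)), function(j) {
    head_w <- str_to_lower(ph$head[j])
    has_concept <- !is.na(ph$cui[j]) || !is.na(ph$drug_family[j])
    has_concept && !head_w %in% c(terms$generic_drug_terms, terms$family_nouns)
  })
  list(semtypes = unique(unlist(ph$semtypes)),
       specific = any(spec),
       number = if (nrow(ph) > 1) "plural" else ph$number[1])
}

#' Build the ordered candidate-center list for an anaphor
#'
#' Candidates are taken from the anaphor's own sentence (phrases wholly
#' preceding it, left to right — salience decreasing) followed by the
#' previous sentence (left to right). Coordinated phrases collapse into a
#' single plural center; an NP parenthetically apposed to another with a
#' shared semantic type joins its center; bare pronoun chunks and other
#' detected anaphors are not centers in their own right — an already
#' resolved anaphor contributes its own antecedent (transitive resolution)
#' and an unresolved one is skipped.
#'
#' @param doc A `drug_document`.
#' @param anaphor_id Phrase ID of the anaphor.
#' @param coords Coordination groups from [detect_coordinations()].
#' @param mentions Mention table from [detect_anaphors()] (other anaphors
#'   are excluded as centers).
#' @param links Links resolved so far (for transitive substitution); may be
#'   `NULL`.
#' @param lexicon,terms Lexical resources.
#' @return A tibble of centers, one row each: `member_ids` (list-column),
#'   `sentence`, `first_pos`, `last_pos`, `number`, `semtypes`
#'   (list-column), `specific`, `is_group`, `cardinality` — ordered by the
#'   centering search order.
#' @export
build_center_list <- function(doc, anaphor_id, coords = detect_coordinations(doc),
                              mentions = detect_anaphors(doc, lexicon, terms),
                              links = NULL, lexicon = default_lexicon(),
                              terms = coref_terms()) {
  ph <- doc$phrases
  ai <- match(anaphor_id, ph$id)
  if (is.na(ai)) abort(sprintf("unknown anaphor phrase id '%s'", anaphor_id))
  a_sent <- ph$sentence[ai]
  a_pos <- ph$pos[ai]
  in_scope <- (ph$sentence == a_sent & ph$pos < a_pos) |
    (ph$sentence == a_sent - 1L)
  cand <- ph[in_scope, , drop = FALSE]
  if (nrow(cand) == 0) return(center_tibble())

  # groups and appositions entirely within scope
  grp <- coords[coords$sentence %in% c(a_sent, a_sent - 1L), , drop = FALSE]
  grp <- grp[map_lgl(grp$member_ids, function(m) all(m %in% cand$id)), ,
             drop = FALSE]
  grouped_ids <- unlist(grp$member_ids)

  appos <- detect_appositions(doc, c(a_sent - 1L, a_sent))
  appos <- appos[map_lgl(appos, function(m) {
    all(m %in% cand$id) && !any(m %in% grouped_ids)
  })]
  appos_ids <- unlist(appos)

  other_anaphors <- setdiff(mentions$phrase_id, anaphor_id)
  resolved_map <- if (!is.null(links) && nrow(links) > 0) {
    stats::setNames(links$antecedent_ids, links$anaphor_id)
  } else list()

  centers <- list()
  add_center <- function(ids, is_group) {
    pos_tbl <- ph[match(ids, ph$id), ]
    f <- features_for_phrases(doc, ids, lexicon, terms)
    centers[[length(centers) + 1]] <<- tibble(
      member_ids = list(ids), sentence = max(pos_tbl$sentence),
      first_pos = min(pos_tbl$pos), last_pos = max(pos_tbl$pos),
      number = f$number, semtypes = list(f$semtypes), specific = f$specific,
      is_group = is_group, cardinality = length(ids))
  }
  for (g in seq_len(nrow(grp))) add_center(grp$member_ids[[g]], TRUE)
  for (m in appos) add_center(m, TRUE)
  singles <- cand[!cand$id %in% c(grouped_ids, appos_ids), , drop = FALSE]
  for (j in seq_len(nrow(singles))) {
    row <- singles[j, ]
    if (!row$type %in% c("NP", "PP")) next
    tok <- row$tokens[[1]]
    if (nrow(tok) == 1 && tok$pos[1] == "PRON") {
      if (row$id %in% names(resolved_map)) {
        sub <- resolved_map[[row$id]]
        if (length(sub) > 0) {
          f <- features_for_phrases(doc, sub, lexicon, terms)
          centers[[length(centers) + 1]] <- tibble(
            member_ids = list(sub), sentence = row$sentence,
            first_pos = row$pos, last_pos = row$pos, number = f$number,
            semtypes = list(f$semtypes), specific = f$specific,
            is_group = length(sub) > 1, cardinality = length(sub))
        }
      }
      next
    }
    if (row$id %in% other_anaphors) {
      if (row$id %in% names(resolved_map) &&
          length(resolved_map[[row$id]]) > 0) {
        sub <- resolved_map[[row$id]]
        f <- features_for_phrases(doc, sub, lexicon, terms)
        centers[[length(centers) + 1]] <- tibble(
          member_ids = list(sub), sentence = row$sentence,
          first_pos = row$pos, last_pos = row$pos, number = f$number,
          semtypes = list(f$semtypes), specific = f$specific,
          is_group = length(sub) > 1, cardinality = length(sub))
      }
      next
    }
    add_center(row$id, FALSE)
  }
  if (length(centers) == 0) return(center_tibble())
  out <- bind_rows(centers)
  # same-sentence candidates first (left to right), then previous sentence
  same <- filter(out, .data$sentence == a_sent) |> arrange(.data$first_pos)
  prev <- filter(out, .data$sentence == a_sent - 1L) |> arrange(.data$first_pos)
  bind_rows(same, prev)
}

center_tibble <- function() {
  tibble(member_ids = list(), sentence = integer(), first_pos = integer(),
         last_pos = integer(), number = character(), semtypes = list(),
         specific = logical(), is_group = logical(), cardinality = integer())
}

detect_appositions <- function(doc, sentences) {
  # NP ( NP ) with a shared semantic type, or an all-caps abbreviation
  out <- list()
  for (si in intersect(sentences, doc$sentences$index)) {
    ph <- filter(doc$phrases, .data$sentence == si)
    if (nrow(ph) < 4) next
    for (j in seq_len(nrow(ph) - 3L)) {
      if (!ph$type[j] %in% c("NP", "PP")) next
      if (!(ph$type[j + 1] == "UNK" && str_trim(ph$text[j + 1]) == "(")) next
      if (!ph$type[j + 2] %in% c("NP", "PP")) next
      if (!(ph$type[j + 3] == "UNK" && str_trim(ph$text[j + 3]) == ")")) next
      shared <- length(intersect(ph$semtypes[[j]], ph$semtypes[[j + 2]])) > 0
      abbrev <- grepl("^[A-Z][A-Za-z]*s?$", ph$head[j + 2]) &&
        ph$head[j + 2] == toupper(ph$head[j + 2])
      if (shared || abbrev) {
        out[[length(out) + 1]] <- c(ph$id[j], ph$id[j + 2])
      }
    }
  }
  out
}

#' Does a candidate center agree with an anaphor?
#'
#' Morphological and semantic agreement: grammatical number must match (a
#' coordination group counts as plural; distributive anaphors instead
#' require a plural or coordinated center, with "both"/"either"/"neither"
#' demanding a two-member coordination); the center must carry at least one
#' drug semantic type (`phsu`, `antb`, `clnd`) — for nominal anaphors
#' always, for pronouns when `semantic_filter_pronouns` is on; and a
#' nominal anaphor's center must be a specific drug (concept-bearing, not a
#' drug family or generic term).
#'
#' @param mention One row of the mention table ([detect_anaphors()]).
#' @param center One row of the center list ([build_center_list()]).
#' @param semantic_filter_pronouns Apply the drug-semantic-type restriction
#'   to pronominal anaphors too (default `TRUE`).
#' @param terms Closed term lists.
#' @return `TRUE` iff all applicable constraints hold.
#' @export
agrees <- function(mention, center, semantic_filter_pronouns = TRUE,
                   terms = coref_terms()) {
  ok_num <- if (mention$subclass == "distributive") {
    if (isTRUE(center$is_group)) {
      if (mention$unit %in% c("both", "either", "neither")) {
        center$cardinality == 2L
      } else TRUE
    } else identical(center$number, "plural")
  } else {
    mention$number == "unknown" || center$number == "unknown" ||
      mention$number == center$number
  }
  if (!ok_num) return(FALSE)
  need_sem <- mention$category == "nominal" || isTRUE(semantic_filter_pronouns)
  if (need_sem &&
      length(intersect(center$semtypes[[1]], terms$drug_semtypes)) == 0) {
    return(FALSE)
  }
  if (mention$category == "nominal" && !isTRUE(center$specific)) return(FALSE)
  TRUE
}

make_link <- function(doc_id, mention, ids, strategy) {
  tibble(doc_id = doc_id, anaphor_id = mention$phrase_id,
         category = mention$category, subclass = mention$subclass,
         strategy = strategy, resolved = length(ids) > 0,
         antecedent_ids = list(sort(ids)))
}

#' Resolve one anaphor by the centering search
#'
#' The first center in the ordered candidate list (same sentence left to
#' right, then previous sentence left to right) that satisfies [agrees()]
#' becomes the single antecedent; with no agreeing center within that
#' two-sentence scope the anaphor is left unresolved.
#'
#' @param doc A `drug_document`.
#' @param mention One mention row.
#' @param centers Ordered center list for this anaphor.
#' @param semantic_filter_pronouns See [agrees()].
#' @param terms Closed term lists.
#' @return A one-row link tibble (`doc_id`, `anaphor_id`, `category`,
#'   `subclass`, `strategy`, `resolved`, `antecedent_ids`).
#' @export
resolve_centering <- function(doc, mention, centers,
                              semantic_filter_pronouns = TRUE,
                              terms = coref_terms()) {
  for (k in seq_len(nrow(centers))) {
    if (agrees(mention, centers[k, ], semantic_filter_pronouns, terms)) {
      return(make_link(doc$doc_id, mention, centers$member_ids[[k]], "centering"))
    }
  }
  make_link(doc$doc_id, mention, character(), "centering")
}

#' Resolve one anaphor by the local closest-match strategy
#'
#' Relative, reflexive and possessive anaphors find their antecedent in the
#' immediately preceding context: the nearest preceding center (right to
#' left, within the current and previous sentence) that satisfies
#' [agrees()].
#'
#' @inheritParams resolve_centering
#' @return A one-row link tibble with strategy `"local"`.
#' @export
resolve_local <- function(doc, mention, centers,
                          semantic_filter_pronouns = TRUE,
                          terms = coref_terms()) {
  ord <- arrange(centers, -.data$sentence, -.data$last_pos)
  for (k in seq_len(nrow(ord))) {
    if (agrees(mention, ord[k, ], semantic_filter_pronouns, terms)) {
      return(make_link(doc$doc_id, mention, ord$member_ids[[k]], "local"))
    }
  }
  make_link(doc$doc_id, mention, character(), "local")
}

#' Resolve one anaphor by the closest-nominal-phrase baseline
#'
#' Selects the nearest preceding NP/PP chunk (bare pronoun chunks excluded)
#' with no agreement checks and no coordination collapsing — the ad-hoc
#' reference strategy the rule-based resolver is compared against.
#'
#' @param doc A `drug_document`.
#' @param mention One mention row.
#' @return A one-row link tibble with strategy `"baseline"`.
#' @export
resolve_baseline <- function(doc, mention) {
  ph <- doc$phrases
  in_scope <- ((ph$sentence == mention$sentence & ph$pos < mention$pos) |
                 ph$sentence == mention$sentence - 1L) &
    ph$type %in% c("NP", "PP")
  cand <- ph[in_scope, , drop = FALSE]
  keep <- map_lgl(seq_len(nrow(cand)), function(j) {
    tok <- cand$tokens[[j]]
    !(nrow(tok) == 1 && tok$pos[1] == "PRON")
  })
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(make_link(doc$doc_id, mention, character(), "baseline"))
  cand <- arrange(cand, -.data$sentence, -.data$pos)
  make_link(doc$doc_id, mention, cand$id[1], "baseline")
}

#' Resolve all anaphors in a document
#'
#' Runs detection, coordination analysis and antecedent selection. Under
#' the `"centering"` strategy, relative and reflexive pronouns and
#' possessive nominals are dispatched to the local closest-match strategy
#' ([resolve_local()]) and every other mention to the centering search
#' ([resolve_centering()]); `"baseline"` sends every mention to
#' [resolve_baseline()]. Anaphors are processed in document order so that a
#' later anaphor whose nearest center is an already-resolved anaphor links
#' transitively to that anaphor's antecedent.
#'
#' @param doc A `drug_document`.
#' @param strategy `"centering"` (the full rule system) or `"baseline"`.
#' @param semantic_filter_pronouns Apply the drug semantic-type restriction
#'   to pronouns as well as nominals (default `TRUE`).
#' @param lexicon,terms Lexical resources.
#' @return A link tibble, one row per detected anaphor: `doc_id`,
#'   `anaphor_id`, `category`, `subclass`, `strategy`, `resolved`,
#'   `antecedent_ids` (list-column).
#' @export
#' @examples
#' doc <- annotate_text(paste(
#'   "Triamterene, metformin and amiloride should be co-administered",
#'   "with care as they might increase dofetilide levels."))
#' resolve_anaphora(doc)
resolve_anaphora <- function(doc, strategy = c("centering", "baseline"),
                             semantic_filter_pronouns = TRUE,
                             lexicon = default_lexicon(),
                             terms = coref_terms()) {
  strategy <- match.arg(strategy)
  mentions <- detect_anaphors(doc, lexicon, terms)
  if (nrow(mentions) == 0) return(empty_links())
  mentions <- arrange(mentions, .data$sentence, .data$pos)
  coords <- detect_coordinations(doc)
  links <- empty_links()
  for (i in seq_len(nrow(mentions))) {
    m <- mentions[i, ]
    link <- if (strategy == "baseline") {
      resolve_baseline(doc, m)
    } else {
      centers <- build_center_list(doc, m$phrase_id, coords, mentions,
                                   links, lexicon, terms)
      local_classes <- (m$category == "pronominal" &&
                          m$subclass %in% c("relative", "reflexive")) ||
        (m$category == "nominal" && m$subclass == "possessive")
      if (local_classes) {
        resolve_local(doc, m, centers, semantic_filter_pronouns, terms)
      } else {
        resolve_centering(doc, m, centers, semantic_filter_pronouns, terms)
      }
    }
    links <- bind_rows(links, link)
  }
  links
}

#' An empty resolution-link table
#' @return A zero-row link tibble with the canonical columns.
#' @export
empty_links <- function() {
  tibble(doc_id = character(), anaphor_id = character(), category = character(),
         subclass = character(), strategy = character(), resolved = logical(),
         antecedent_ids = list())
}

#' Resolve every document of a corpus
#'
#' @param corpus An `anaphora_corpus` (see [generate_corpus()]) or a plain
#'   list of `drug_document`s.
#' @inheritParams resolve_anaphora
#' @return The row-bound link tibble over all documents.
#' @export
resolve_corpus <- function(corpus, strategy = c("centering", "baseline"),
                           semantic_filter_pronouns = TRUE,
                           lexicon = default_lexicon(), terms = coref_terms()) {
  strategy <- match.arg(strategy)
  docs <- if (inherits(corpus, "anaphora_corpus")) corpus$documents else corpus
  bind_rows(map(docs, resolve_anaphora, strategy = strategy,
                semantic_filter_pronouns = semantic_filter_pronouns,
                lexicon = lexicon, terms = terms))
}
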