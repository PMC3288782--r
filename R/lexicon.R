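# Bundled lexical resources: the mini-lexicon standing in for UMLS concept
# lookup, the WHO INN stem table used for drug-family classification, and the
# closed word lists the detection rules quantify over.

#' Read a concept lexicon from a TSV file
#'
#' The lexicon maps lowercased surface forms to a concept identifier (CUI),
#' a preferred concept name and a set of UMLS-style semantic type
#' abbreviations (e.g. `phsu` pharmacological substance, `antb` antibiotic,
#' `orch` organic chemical, `qlco` qualitative concept). Lookup through
#' [lexicon_lookup()] is case-insensitive and longest-match-first for
#' multiword spans.
#'
#' @param path Path to a TSV file with columns `surface`, `cui`, `concept`,
#'   `semtypes` (comma-separated).
#' @return A tibble of class `coref_lexicon` with columns `surface`, `cui`,
#'   `concept` and a list-column `semtypes`.
#' @seealso [default_lexicon()] for the bundled resource.
#' @export
#' @examples
#' lex <- default_lexicon()
#' lexicon_lookup(lex, "Aprazolam")
read_lexicon <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                           colClasses = "character")
  need <- c("surface", "cui", "concept", "semtypes")
  if (!all(need %in% names(raw))) {
    abort(paste0("lexicon file must have columns ", paste(need, collapse = ", ")))
  }
  lex <- tibble::as_tibble(raw) |>
    mutate(
      surface = str_to_lower(str_trim(.data$surface)),
      cui = ifelse(str_trim(.data$cui) == "", NA_character_, str_trim(.data$cui)),
      semtypes = map(str_split(.data$semtypes, ","),
                     function(x) setdiff(str_trim(x), ""))
    )
  if (anyDuplicated(lex$surface)) {
    abort("duplicate surface forms in lexicon")
  }
  structure(lex, class = c("coref_lexicon", class(lex)))
}

#' Bundled mini-lexicon of drug concepts
#'
#' A curated stand-in for live UMLS Metathesaurus access: the drugs named in
#' typical interaction passages plus qualitative-concept nouns (drug
#' properties and effects, semantic type `qlco`).
#'
#' @return A `coref_lexicon` tibble (see [read_lexicon()]).
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.tsv", package = "pharmacoref"))
}

#' Look up a surface form in a lexicon
#'
#' @param lexicon A `coref_lexicon` from [read_lexicon()].
#' @param surface Character vector of surface forms (any case).
#' @return A tibble with one row per input: `surface`, `cui`, `concept`,
#'   `semtypes` (list); unmatched forms get `NA` / empty types.
#' @export
lexicon_lookup <- function(lexicon, surface) {
  key <- str_to_lower(surface)
  idx <- match(key, lexicon$surface)
  tibble(
    surface = surface,
    cui = lexicon$cui[idx],
    concept = lexicon$concept[idx],
    semtypes = map(idx, function(i) if (is.na(i)) character() else lexicon$semtypes[[i]])
  )
}

#' Read a WHO INN affix table from a TSV file
#'
#' International Nonproprietary Name (INN) stems identify a drug's
#' pharmacological family from its name alone (e.g. `-azolam` marks a
#' benzodiazepine derivative). The table is kept sorted longest-suffix-first
#' so that the most specific stem wins (`-prazole` before `-azole`).
#'
#' @param path Path to a TSV file with columns `suffix`, `family`.
#' @return A tibble of class `inn_affix_table` with columns `suffix`
#'   (lowercase, no leading dash) and `family`, ordered by decreasing
#'   suffix length.
#' @export
read_affix_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("suffix", "family") %in% names(raw))) {
    abort("affix table must have columns suffix, family")
  }
  tab <- tibble::as_tibble(raw) |>
    mutate(suffix = sub("^-", "", str_to_lower(str_trim(.data$suffix)))) |>
    arrange(-nchar(.data$suffix))
  if (anyDuplicated(tab$suffix)) abort("duplicate suffixes in affix table")
  structure(tab, class = c("inn_affix_table", class(tab)))
}

#' Bundled WHO INN stem table
#'
#' A curated subset of WHO INN stems sufficient for the drug families that
#' occur in interaction prose; see `inst/extdata/inn_stems.tsv`.
#'
#' @return An `inn_affix_table` tibble (see [read_affix_table()]).
#' @export
default_affix_table <- function() {
  read_affix_table(system.file("extdata", "inn_stems.tsv", package = "pharmacoref"))
}

#' Closed word lists used by the detection and agreement rules
#'
#' @description
#' Term lists the rule system quantifies over:
#' * `generic_drug_terms`: generic nouns for drugs ("drug", "medication",
#'   ...) that head abstract nominal anaphors.
#' * `family_nouns`: drug-family plural/singular nouns ("anticoagulants",
#'   "SSRIs", ...).
#' * `qualitative_terms`: property/effect nouns mapped to semantic type
#'   `qlco`.
#' * `drug_semtypes`: semantic types a drug antecedent must carry.
#'
#' @return A named list of character vectors.
#' @export
coref_terms <- function() {
  list(
    generic_drug_terms = c(
      "drug", "drugs", "medicine", "medicines", "medication", "medications",
      "agent", "agents", "antibiotic", "antibiotics", "therapy",
      "compound", "compounds"),
    family_nouns = c(
      "anticoagulant", "anticoagulants", "antidepressant", "antidepressants",
      "benzodiazepine", "benzodiazepines", "ssri", "ssris",
      "diuretic", "diuretics", "analgesic", "analgesics",
      "antihypertensive", "antihypertensives", "barbiturate", "barbiturates",
      "opioid", "opioids", "statin", "statins", "salicylate", "salicylates",
      "contraceptive", "contraceptives", "inhibitor", "inhibitors",
      "blocker", "blockers", "inducer", "inducers"),
    qualitative_terms = c(
      "effect", "effects", "property", "properties", "activity",
      "activities", "action", "actions"),
    drug_semtypes = c("phsu", "antb", "clnd")
  )
}

#' Classify a drug name into its pharmacological family by INN affix
#'
#' Matches the longest INN stem that is a proper suffix of the name,
#' case-insensitively. `"aprazolam"` classifies as `"Benzodiazepine
#' derivative"` via the stem `-azolam`.
#'
#' @param drug_name Character vector of drug names.
#' @param affixes An `inn_affix_table`; defaults to the bundled table.
#' @return Character vector of family names, `NA` where no stem matches.
#' @export
#' @examples
#' classify_inn_affix(c("aprazolam", "propranolol", "zzzz"))
classify_inn_affix <- function(drug_name, affixes = default_affix_table()) {
  low <- str_to_lower(drug_name)
  map_chr(low, function(w) {
    if (is.na(w) || !nzchar(w)) return(NA_character_)
    for (i in seq_len(nrow(affixes))) {
      suf <- affixes$suffix[i]
      # proper suffix: the name must be longer than the stem itself
      if (nchar(w) > nchar(suf) && endsWith(w, suf)) return(affixes$family[i])
    }
    NA_character_
  })
}
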