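# Hand-encoded worked examples: the canonical interaction sentences that
# exercise every rule family (coordination, possessive and pronominal
# anaphora, pleonastic-it, correlative constructions, and an annotated
# MMTx-style sentence with verbatim phrase IDs).

find_phrase_id <- function(doc, pattern) {
  hit <- which(str_detect(str_to_lower(doc$phrases$text),
                          stringr::fixed(str_to_lower(pattern))))
  if (length(hit) == 0) abort(sprintf("no phrase matching '%s'", pattern))
  doc$phrases$id[hit[1]]
}

example_coordinated_possessive <- function(lexicon, affixes) {
  doc <- annotate_text(paste(
    "Although beta-adrenergic blockers or calcium channel blockers and",
    "digoxin may be useful in combination to control atrial fibrillation,",
    "their additive effects on AV node conduction can result in advanced",
    "or complete heart block."),
    doc_id = "ex_coordinated_possessive", lexicon = lexicon, affixes = affixes)
  doc$gold <- tibble(
    anaphor_id = find_phrase_id(doc, "additive effects"),
    antecedent_ids = list(sort(c(
      find_phrase_id(doc, "beta-adrenergic blockers"),
      find_phrase_id(doc, "calcium channel blockers"),
      find_phrase_id(doc, "digoxin")))),
    category = "nominal", subclass = "possessive")
  validate_document(doc)
  doc
}

example_plural_pronoun <- function(lexicon, affixes) {
  doc <- annotate_text(paste(
    "In addition triamterene, metformin and amiloride should be",
    "co-administered with care as they might increase dofetilide levels."),
    doc_id = "ex_plural_pronoun", lexicon = lexicon, affixes = affixes)
  doc$gold <- tibble(
    anaphor_id = find_phrase_id(doc, "they"),
    antecedent_ids = list(sort(c(
      find_phrase_id(doc, "triamterene"),
      find_phrase_id(doc, "metformin"),
      find_phrase_id(doc, "amiloride")))),
    category = "pronominal", subclass = "personal")
  validate_document(doc)
  doc
}

# The annotated MMTx-style sentence with its published phrase IDs: "it"
# (s28.p378) refers to "of fluvoxamine" (s28.p371). IDs are preserved
# verbatim; they are not monotone in surface order in this hand encoding,
# which read/write round-trips but annotate_text would never produce.
example_annotated_sentence <- function() {
  fill <- map(0:27, function(i) {
    tok <- token_tibble(c("See", "prescribing", "information", "."),
                        pos = c("VERB", "NOUN", "NOUN", "PUNCT"))
    phrase_row(sprintf("s%d.p%d", i, i + 1L), i, 0L, "UNK", tok,
               head_index = 3L)
  })
  tok28 <- list(
    phrase_row("s28.p366", 28L, 0L, "NP",
               token_tibble(c("Plasma", "concentrations"), c("NOUN", "NOUN")),
               head_index = 2L, number = "plural"),
    phrase_row("s28.p371", 28L, 1L, "PP",
               token_tibble(c("of", "fluvoxamine"), c("PREP", "NOUN")),
               head_index = 2L, cui = "C0085228", concept = "Fluvoxamine",
               semtypes = c("orch", "phsu"), number = "singular"),
    phrase_row("s28.p373", 28L, 2L, "VP",
               token_tibble(c("increased", "markedly"), c("VERB", "ADV"))),
    phrase_row("s28.p375", 28L, 3L, "PP",
               token_tibble(c("during", "combined", "treatment"),
                            c("PREP", "ADJ", "NOUN")),
               head_index = 3L, number = "singular"),
    phrase_row("s28.p369", 28L, 4L, "PP",
               token_tibble(c("with", "aprazolam"), c("PREP", "NOUN")),
               head_index = 2L, cui = "C0002333", concept = "Alprazolam",
               semtypes = c("orch", "phsu"),
               drug_family = "Benzodiazepine derivative", number = "singular"),
    phrase_row("s28.p376", 28L, 5L, "CONJ", token_tibble("and", "CONJ")),
    phrase_row("s28.p378", 28L, 6L, "NP", token_tibble("it", "PRON"),
               number = "singular"),
    phrase_row("s28.p379", 28L, 7L, "VP",
               token_tibble(c("was", "poorly", "tolerated"),
                            c("VERB", "ADV", "VERB"))))
  sents <- tibble(
    index = 0:28,
    text = c(rep("See prescribing information.", 28),
             paste("Plasma concentrations of fluvoxamine increased markedly",
                   "during combined treatment with aprazolam and it was",
                   "poorly tolerated.")))
  gold <- tibble(anaphor_id = "s28.p378", antecedent_ids = list("s28.p371"),
                 category = "pronominal", subclass = "personal")
  drug_document("ex_annotated_sentence", sents, bind_rows(c(fill, tok28)),
                gold, source = "hand-encoded")
}

example_pleonastic <- function(lexicon, affixes) {
  annotate_text(paste(
    "It is not known whether other progestational contraceptives are",
    "adequate methods of contraception during acitretin therapy.",
    "If it is not possible to discontinue the diuretic, the starting dose",
    "of trandolapril should be reduced.",
    "It does not appear that the SSRIs reduce the effectiveness of a mood",
    "stabilizer in these populations."),
    doc_id = "ex_pleonastic", lexicon = lexicon, affixes = affixes)
}

example_correlative <- function(lexicon, affixes) {
  annotate_text(paste(
    "These pharmacokinetic effects seen during diltiazem coadministration",
    "can result in increased clinical effects ( e.g., prolonged sedation )",
    "of both midazolam and triazolam."),
    doc_id = "ex_correlative", lexicon = lexicon, affixes = affixes)
}

example_coordination_list <- function(lexicon, affixes) {
  doc <- annotate_text(paste(
    "While all the selective serotonin reuptake inhibitors ( SSRIs ) e.g.",
    "fluoxetine, sertraline and paroxetine inhibit P450 2D6, they may vary",
    "in the extent of inhibition."),
    doc_id = "ex_coordination_list", lexicon = lexicon, affixes = affixes)
  doc$gold <- tibble(
    anaphor_id = find_phrase_id(doc, "they"),
    antecedent_ids = list(sort(c(
      find_phrase_id(doc, "fluoxetine"),
      find_phrase_id(doc, "sertraline"),
      find_phrase_id(doc, "paroxetine")))),
    category = "pronominal", subclass = "personal")
  validate_document(doc)
  doc
}

# Effect-for-drug metonymy: resolving "the antidepressant effect" to
# venlafaxine needs drug-family semantics the rule system deliberately does
# not use, so this gold link is flagged unresolvable by design.
example_effect_metonymy <- function(lexicon, affixes) {
  doc <- annotate_text(paste(
    "Coadministration of naloxone with venlafaxine did not modify the",
    "antidepressant effect."),
    doc_id = "ex_effect_metonymy", lexicon = lexicon, affixes = affixes)
  doc$gold <- tibble(
    anaphor_id = find_phrase_id(doc, "antidepressant effect"),
    antecedent_ids = list(find_phrase_id(doc, "venlafaxine")),
    category = "nominal", subclass = "definite")
  attr(doc, "out_of_rules") <- doc$gold$anaphor_id
  validate_document(doc)
  doc
}

#' Bundled worked-example documents
#'
#' Hand-encoded fixture documents covering the rule inventory: a
#' three-drug coordination with a possessive anaphor, a plural personal
#' pronoun over a coordinated list, an annotated MMTx-style sentence with
#' verbatim phrase IDs (gold: "it" -> "of fluvoxamine", s28.p371), three
#' pleonastic-it sentences, a correlative "both ... and" construction, an
#' SSRI enumeration yielding a three-member coordination group, and an
#' effect-for-drug metonymy marked unresolvable by design.
#'
#' @param lexicon,affixes Lexical resources used to annotate the plain-text
#'   examples.
#' @return An `anaphora_corpus` whose `documents` are the examples (keyed
#'   by name) and whose `gold` combines their annotations.
#' @export
#' @examples
#' ex <- reference_examples()
#' names(ex$documents)
reference_examples <- function(lexicon = default_lexicon(),
                               affixes = default_affix_table()) {
  docs <- list(
    example_coordinated_possessive(lexicon, affixes),
    example_plural_pronoun(lexicon, affixes),
    example_annotated_sentence(),
    example_pleonastic(lexicon, affixes),
    example_correlative(lexicon, affixes),
    example_coordination_list(lexicon, affixes),
    example_effect_metonymy(lexicon, affixes))
  names(docs) <- map_chr(docs, function(d) d$doc_id)
  structure(list(documents = docs, gold = corpus_gold(docs),
                 config = list(source = "bundled worked examples")),
            class = "anaphora_corpus")
}
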