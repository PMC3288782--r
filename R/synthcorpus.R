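# Seeded generator of gold-annotated synthetic interaction documents.
# Documents are template-built from parameterised sentence frames (data
# file, not code), INN-composed drug names, family nouns, generic drug
# terms and interaction verbs; each generated anaphor has exactly one
# agreeing candidate in scope (its gold antecedent) so that, with no
# distractors, the rule-based resolver recovers every link.

#' Default anaphor-class distribution
#'
#' Proportions of the 11 anaphor classes (6 pronominal, 5 nominal) as they
#' occur in annotated drug-interaction corpora: relative pronouns and
#' demonstrative/possessive nominals dominate.
#'
#' @return A named numeric vector over classes
#'   (`"pronominal_personal"`, ..., `"nominal_indefinite"`) summing to 1.
#' @export
default_anaphor_mix <- function() {
  counts <- c(
    pronominal_personal = 23, pronominal_reflexive = 1,
    pronominal_relative = 113, pronominal_distributive = 8,
    pronominal_demonstrative = 12, pronominal_indefinite = 8,
    nominal_definite = 37, nominal_possessive = 52,
    nominal_distributive = 11, nominal_demonstrative = 58,
    nominal_indefinite = 8)
  counts / sum(counts)
}

#' Read the sentence-frame inventory
#'
#' Frames are parameterised sentence templates (`{D1}`..`{D4}` drug slots,
#' `{G}`/`{Gs}` generic drug terms, `{X}` optional distractor slot)
#' covering every anaphor class plus pleonastic-it, correlative and plain
#' filler sentences. They live in a data file so coverage can grow without
#' code change.
#'
#' @param path TSV file with columns `kind`, `class`, `anaphor_head`,
#'   `antecedents`, `template`; defaults to the bundled inventory.
#' @return A tibble of frames.
#' @export
read_frames <- function(path = system.file("extdata", "frames.tsv",
                                           package = "pharmacoref")) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                      na.strings = NULL,
                                      colClasses = "character"))
}

GENERIC_SINGULAR <- c("drug", "medication", "medicine", "agent", "compound")
DISTRACTORS <- c("in elderly patients", "after prolonged treatment",
                 "during the first treatment week", "under close supervision")
NAME_SYLLABLES <- c(
  "lor", "flu", "var", "tri", "keto", "ami", "dex", "pro", "met", "carb",
  "riv", "osel", "phen", "ben", "cit", "dul", "esc", "fex", "gab", "hal",
  "lam", "mir", "nev", "pir", "quen", "ros", "sev", "teb", "vand", "zop",
  "alm", "bri", "cor", "dro", "fos", "gly", "hyd", "ida", "kal", "lum",
  "mav", "nor", "oct", "pam", "rud", "sab", "tam", "vex", "xan", "zeb")
NAME_SUFFIXES <- c(
  "azolam", "olol", "oxetine", "pril", "sartan", "statin", "dipine",
  "tidine", "prazole", "floxacin", "cillin", "mycin", "profen", "caine",
  "thiazide", "formin", "triptan", "setron", "zosin", "terol")

make_drug_namer <- function(lexicon) {
  used <- character()
  function() {
    for (try in 1:100) {
      nm <- paste0(paste(sample(NAME_SYLLABLES, sample(1:2, 1)), collapse = ""),
                   sample(NAME_SUFFIXES, 1))
      if (!nm %in% used && !nm %in% lexicon$surface) {
        used <<- c(used, nm)
        return(nm)
      }
    }
    abort("could not generate a fresh drug name")
  }
}

fill_frame <- function(template, namer, distractor_on) {
  vals <- list()
  for (slot in c("D1", "D2", "D3", "D4")) {
    pat <- paste0("{", slot, "}")
    if (grepl(pat, template, fixed = TRUE)) {
      vals[[slot]] <- namer()
      template <- gsub(pat, vals[[slot]], template, fixed = TRUE)
    }
  }
  if (grepl("{G}", template, fixed = TRUE) || grepl("{Gs}", template, fixed = TRUE)) {
    g <- sample(GENERIC_SINGULAR, 1)
    vals[["G"]] <- g
    vals[["Gs"]] <- paste0(g, "s")
    template <- gsub("{G}", g, template, fixed = TRUE)
    template <- gsub("{Gs}", paste0(g, "s"), template, fixed = TRUE)
  }
  if (grepl("{X}", template, fixed = TRUE)) {
    x <- if (distractor_on) paste0(" ", sample(DISTRACTORS, 1)) else ""
    template <- gsub("{X}", x, template, fixed = TRUE)
  }
  # capitalise sentence starts (drug slots may open a sentence)
  template <- gsub("(^|\\. )([a-z])", "\\1\\U\\2", template, perl = TRUE)
  list(text = template, values = vals)
}

find_block_phrase <- function(doc, sent_range, head_word) {
  ph <- filter(doc$phrases, .data$sentence %in% sent_range,
               .data$type %in% c("NP", "PP"),
               str_to_lower(.data$head) == str_to_lower(head_word))
  if (nrow(ph) == 0) {
    abort(sprintf("generator integrity: head '%s' not found in sentences %s of %s",
                  head_word, paste(range(sent_range), collapse = "-"), doc$doc_id))
  }
  ph$id[1]
}

#' Generate a gold-annotated synthetic corpus
#'
#' Builds `n_documents` documents from the bundled sentence frames: a
#' sampled number of anaphor blocks per document (each block a one- or
#' two-sentence frame whose gold antecedent is the unique agreeing
#' candidate in scope), padded with plain, pleonastic-it and correlative
#' filler sentences, shuffled at the block level so locality is preserved.
#' With `distractor_rate > 0`, non-agreeing noun phrases are injected
#' between antecedent and anaphor, which degrades a proximity baseline but
#' not agreement-checked resolution. Documents are run through the full
#' [annotate_text()] pipeline, so generated INN-suffixed drug names
#' exercise family classification end to end.
#'
#' @param n_documents Number of documents (49 emulates a DrugBank-scale
#'   interaction corpus).
#' @param sentences_per_document Target sentences per document (mean of the
#'   emulated corpus: 40).
#' @param anaphors_per_document Mean anaphors per document; default 331/49,
#'   sampled per document from a Poisson (minimum 1).
#' @param anaphor_mix Named distribution over the 11 anaphor classes
#'   (must sum to 1); see [default_anaphor_mix()].
#' @param distractor_rate Probability that an anaphor block carries an
#'   injected non-agreeing distractor phrase.
#' @param pleonastic_rate,correlative_rate Probability that a filler slot
#'   is a pleonastic-it / correlative sentence rather than a plain one.
#' @param seed Optional integer; the same seed yields an identical corpus.
#' @param lexicon,affixes Lexical resources for the annotation pipeline.
#' @return An `anaphora_corpus`: list with `documents` (named list of
#'   [drug_document()]s, each carrying its gold), `gold` (combined tibble
#'   with `doc_id`) and `config`.
#' @export
#' @examples
#' corp <- generate_corpus(n_documents = 2, sentences_per_document = 10, seed = 1)
#' corp$gold
generate_corpus <- function(n_documents = 49, sentences_per_document = 40,
                            anaphors_per_document = 331 / 49,
                            anaphor_mix = default_anaphor_mix(),
                            distractor_rate = 0, pleonastic_rate = 0.08,
                            correlative_rate = 0.08, seed = NULL,
                            lexicon = default_lexicon(),
                            affixes = default_affix_table()) {
  if (abs(sum(anaphor_mix) - 1) > 1e-8 || any(anaphor_mix < 0)) {
    abort("anaphor_mix must be a non-negative distribution summing to 1")
  }
  frames <- read_frames()
  build <- function() {
    docs <- list()
    gold_all <- list()
    for (d in seq_len(n_documents)) {
      doc_id <- sprintf("synth%03d", d)
      namer <- make_drug_namer(lexicon)
      n_ana <- max(1L, rpois(1, anaphors_per_document))
      classes <- sample(names(anaphor_mix), n_ana, replace = TRUE,
                        prob = anaphor_mix)
      blocks <- list()
      for (cl in classes) {
        fr <- filter(frames, .data$kind == "anaphor", .data$class == cl)
        fr <- fr[sample(nrow(fr), 1), ]
        filled <- fill_frame(fr$template, namer, runif(1) < distractor_rate)
        head_final <- fr$anaphor_head
        for (nm in names(filled$values)) {
          head_final <- gsub(paste0("{", nm, "}"), filled$values[[nm]],
                             head_final, fixed = TRUE)
        }
        ant_heads <- map_chr(str_split(fr$antecedents, ",")[[1]], function(s) {
          filled$values[[str_trim(s)]]
        })
        blocks[[length(blocks) + 1]] <- list(
          lines = split_sentences(filled$text), kind = "anaphor",
          class = cl, anaphor_head = head_final, ant_heads = ant_heads)
      }
      n_fill <- max(0L, sentences_per_document -
                      sum(map_int(blocks, function(b) length(b$lines))))
      for (k in seq_len(n_fill)) {
        u <- runif(1)
        kind <- if (u < pleonastic_rate) "pleonastic"
        else if (u < pleonastic_rate + correlative_rate) "correlative"
        else "filler"
        fr <- filter(frames, .data$kind == !!kind)
        fr <- fr[sample(nrow(fr), 1), ]
        filled <- fill_frame(fr$template, namer, FALSE)
        blocks[[length(blocks) + 1]] <- list(
          lines = split_sentences(filled$text), kind = kind)
      }
      blocks <- blocks[sample(length(blocks))]
      all_lines <- unlist(map(blocks, function(b) b$lines))
      doc <- annotate_text(paste(all_lines, collapse = " "), doc_id = doc_id,
                           lexicon = lexicon, affixes = affixes)
      if (nrow(doc$sentences) != length(all_lines)) {
        abort(sprintf("generator integrity: sentence count mismatch in %s", doc_id))
      }
      offsets <- cumsum(c(0L, head(map_int(blocks, function(b) length(b$lines)), -1)))
      gold_rows <- list()
      for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]
        if (b$kind != "anaphor") next
        rng <- offsets[bi] + seq_along(b$lines) - 1L
        cls <- str_split(b$class, "_", n = 2)[[1]]
        gold_rows[[length(gold_rows) + 1]] <- tibble(
          anaphor_id = find_block_phrase(doc, rng, b$anaphor_head),
          antecedent_ids = list(sort(map_chr(b$ant_heads, find_block_phrase,
                                             doc = doc, sent_range = rng))),
          category = cls[1], subclass = cls[2])
      }
      gold <- if (length(gold_rows) == 0) empty_gold() else bind_rows(gold_rows)
      doc$gold <- gold
      validate_document(doc)
      docs[[doc_id]] <- doc
      gold_all[[doc_id]] <- mutate(gold, doc_id = doc_id, .before = 1)
    }
    structure(
      list(documents = docs, gold = bind_rows(gold_all),
           config = list(n_documents = n_documents,
                         sentences_per_document = sentences_per_document,
                         anaphors_per_document = anaphors_per_document,
                         anaphor_mix = anaphor_mix,
                         distractor_rate = distractor_rate,
                         pleonastic_rate = pleonastic_rate,
                         correlative_rate = correlative_rate, seed = seed)),
      class = "anaphora_corpus")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @export
print.anaphora_corpus <- function(x, ...) {
  cat(sprintf("<anaphora_corpus: %d document(s), %d sentence(s), %d gold anaphor(s)>\n",
              length(x$documents),
              sum(map_int(x$documents, function(d) nrow(d$sentences))),
              nrow(x$gold)))
  invisible(x)
}

#' Combined gold table of a corpus
#'
#' @param corpus An `anaphora_corpus`, or a list of `drug_document`s whose
#'   embedded gold tables are combined.
#' @return A gold tibble with a `doc_id` column.
#' @export
corpus_gold <- function(corpus) {
  if (inherits(corpus, "anaphora_corpus")) return(corpus$gold)
  out <- bind_rows(map(corpus, function(d) {
    if (nrow(d$gold) == 0) return(NULL)
    mutate(d$gold, doc_id = d$doc_id, .before = 1)
  }))
  if (nrow(out) == 0) out <- mutate(empty_gold(), doc_id = character(), .before = 1)
  out
}
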