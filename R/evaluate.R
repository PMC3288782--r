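# Link-level scoring against gold annotations: per-type and global
# precision, recall, balanced F (beta = 1) and increment over baseline.

#' Balanced F-score
#'
#' Harmonic mean of precision and recall (beta = 1): `F = 2PR / (P + R)`,
#' with `F = 0` when `P + R = 0`.
#'
#' @param p,r Precision and recall in `[0, 1]` (vectorised).
#' @return The balanced F-score.
#' @export
#' @examples
#' f_score(0.84, 0.70)
f_score <- function(p, r) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE),
            all(r >= 0 & r <= 1, na.rm = TRUE))
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Relative increment of one F-score over another
#'
#' `(F_approach - F_baseline) / F_baseline`; when the baseline F is zero
#' the increment is reported as `Inf` (the report prints the infinity
#' sentinel), or 0 when both are zero.
#'
#' @param f_approach,f_baseline F-scores (vectorised).
#' @return The relative increment.
#' @export
#' @examples
#' f_increment(0.76, 0.44)
f_increment <- function(f_approach, f_baseline) {
  ifelse(f_baseline > 0, (f_approach - f_baseline) / f_baseline,
         ifelse(f_approach > 0, Inf, 0))
}

same_set <- function(a, b) {
  length(a) == length(b) && setequal(a, b)
}

#' Score predicted resolution links against gold annotations
#'
#' A prediction is correct iff its antecedent ID set equals the gold set
#' (strict set equality; partial overlap on coordination centers counts as
#' wrong). Precision is `correct / resolved predictions` (0 when nothing is
#' resolved), recall is `correct / n_gold`. Per-class rows are keyed by the
#' gold class; predictions with no gold counterpart count against the
#' precision of their detected class.
#'
#' @param links Link tibble from [resolve_anaphora()] / [resolve_corpus()]
#'   (must carry `doc_id`).
#' @param gold Gold tibble with `doc_id`, `anaphor_id`, `antecedent_ids`
#'   (list-column), `category`, `subclass`.
#' @param doc_ids Optional explicit document universe; any link or gold
#'   row referencing a document outside it raises an input error naming
#'   the offender.
#' @return An object of class `anaphora_eval` with per-class and global
#'   counts and metrics; see [tidy.anaphora_eval()].
#' @export
score_links <- function(links, gold, doc_ids = NULL) {
  if (!is.null(doc_ids)) {
    bad <- setdiff(unique(c(links$doc_id, gold$doc_id)), doc_ids)
    if (length(bad) > 0) {
      abort(sprintf("mismatched document id '%s' not in the evaluated set", bad[1]))
    }
  }
  gold <- mutate(gold, .gold = TRUE)
  merged <- full_join(
    links, gold, by = c("doc_id", "anaphor_id"),
    suffix = c("_pred", "_gold"))
  merged <- mutate(
    merged,
    category = dplyr::coalesce(.data$category_gold, .data$category_pred),
    subclass = dplyr::coalesce(.data$subclass_gold, .data$subclass_pred),
    in_gold = !is.na(.data$.gold),
    resolved = !is.na(.data$resolved) & .data$resolved,
    detected = !is.na(.data$strategy),
    correct = map_lgl(seq_len(dplyr::n()), function(i) {
      isTRUE(merged$resolved[i]) && !is.na(merged$.gold[i]) &&
        same_set(merged$antecedent_ids_pred[[i]], merged$antecedent_ids_gold[[i]])
    }))
  by_class <- merged |>
    group_by(.data$category, .data$subclass) |>
    summarise(
      n_gold = sum(.data$in_gold),
      detected = sum(.data$detected & .data$in_gold),
      resolved = sum(.data$resolved),
      correct = sum(.data$correct),
      .groups = "drop") |>
    mutate(
      precision = ifelse(.data$resolved == 0, 0, .data$correct / .data$resolved),
      recall = ifelse(.data$n_gold == 0, 0, .data$correct / .data$n_gold),
      f = f_score(.data$precision, .data$recall)) |>
    arrange(.data$category, .data$subclass)
  g <- list(
    n_gold = sum(by_class$n_gold), detected = sum(by_class$detected),
    resolved = sum(by_class$resolved), correct = sum(by_class$correct))
  g$precision <- if (g$resolved == 0) 0 else g$correct / g$resolved
  g$recall <- if (g$n_gold == 0) 0 else g$correct / g$n_gold
  g$f <- f_score(g$precision, g$recall)
  structure(list(by_class = by_class, global = tibble::as_tibble(g)),
            class = "anaphora_eval")
}

#' @export
print.anaphora_eval <- function(x, ...) {
  cat("Anaphora resolution evaluation\n")
  cat(sprintf("  gold: %d  resolved: %d  correct: %d\n",
              x$global$n_gold, x$global$resolved, x$global$correct))
  cat(sprintf("  P = %.2f  R = %.2f  F = %.2f\n",
              x$global$precision, x$global$recall, x$global$f))
  print(x$by_class)
  invisible(x)
}

#' Tidy an anaphora evaluation into a per-class tibble
#'
#' @param x An `anaphora_eval`.
#' @param ... Unused.
#' @return The per-class metric tibble with a trailing global row
#'   (`category = "all"`, `subclass = "global"`).
#' @export
tidy.anaphora_eval <- function(x, ...) {
  bind_rows(x$by_class,
            mutate(x$global, category = "all", subclass = "global"))
}

#' One-row summary of an anaphora evaluation
#'
#' @param x An `anaphora_eval`.
#' @param ... Unused.
#' @return A one-row tibble with global counts, precision, recall and F.
#' @export
glance.anaphora_eval <- function(x, ...) x$global

#' Per-type comparison report: baseline vs approach
#'
#' The standard result layout: one row per anaphor class with gold total,
#' baseline P/R/F, approach P/R/F and the relative increment of the
#' approach F over the baseline F (infinite when the baseline F is 0),
#' plus per-category and overall global rows.
#'
#' @param baseline An `anaphora_eval` for the baseline strategy.
#' @param approach An `anaphora_eval` for the rule-based approach.
#' @return An object of class `coref_report`; `tidy()` returns its table.
#' @export
coref_report <- function(baseline, approach) {
  if (!identical(sum(baseline$by_class$n_gold), sum(approach$by_class$n_gold))) {
    abort("baseline and approach were scored against different gold sets")
  }
  b <- select(tidy(baseline), "category", "subclass", "n_gold",
              p_baseline = "precision", r_baseline = "recall", f_baseline = "f")
  a <- select(tidy(approach), "category", "subclass",
              p_approach = "precision", r_approach = "recall", f_approach = "f")
  tab <- full_join(b, a, by = c("category", "subclass")) |>
    mutate(dplyr::across(dplyr::where(is.numeric), function(v) ifelse(is.na(v), 0, v)),
           increment = f_increment(.data$f_approach, .data$f_baseline))
  # per-category subtotals
  cat_rows <- bind_rows(map(c("pronominal", "nominal"), function(categ) {
    bb <- filter(baseline$by_class, .data$category == categ)
    aa <- filter(approach$by_class, .data$category == categ)
    if (nrow(bb) == 0 && nrow(aa) == 0) return(NULL)
    agg <- function(d) {
      p <- if (sum(d$resolved) == 0) 0 else sum(d$correct) / sum(d$resolved)
      r <- if (sum(d$n_gold) == 0) 0 else sum(d$correct) / sum(d$n_gold)
      c(p = p, r = r, f = f_score(p, r), n = sum(d$n_gold))
    }
    vb <- agg(bb); va <- agg(aa)
    tibble(category = categ, subclass = "global", n_gold = unname(vb["n"]),
           p_baseline = unname(vb["p"]), r_baseline = unname(vb["r"]),
           f_baseline = unname(vb["f"]), p_approach = unname(va["p"]),
           r_approach = unname(va["r"]), f_approach = unname(va["f"]),
           increment = f_increment(unname(va["f"]), unname(vb["f"])))
  }))
  tab <- bind_rows(filter(tab, .data$subclass != "global"), cat_rows,
                   filter(tab, .data$subclass == "global"))
  structure(list(table = tab), class = "coref_report")
}

#' @export
tidy.coref_report <- function(x, ...) x$table

#' @export
print.coref_report <- function(x, ...) {
  t <- x$table
  fmt <- function(v) sprintf("%.2f", v)
  inc <- ifelse(is.infinite(t$increment), "Inf", fmt(t$increment))
  cat(sprintf("%-28s %6s  %5s %5s %5s   %5s %5s %5s  %6s\n",
              "class", "total", "P", "R", "F", "P", "R", "F", "Inc"))
  cat(sprintf("%-28s %6s  %17s   %17s\n", "", "", "--- baseline ---",
              "--- approach ---"))
  for (i in seq_len(nrow(t))) {
    cat(sprintf("%-28s %6d  %5s %5s %5s   %5s %5s %5s  %6s\n",
                paste(t$category[i], t$subclass[i]), t$n_gold[i],
                fmt(t$p_baseline[i]), fmt(t$r_baseline[i]), fmt(t$f_baseline[i]),
                fmt(t$p_approach[i]), fmt(t$r_approach[i]), fmt(t$f_approach[i]),
                inc[i]))
  }
  invisible(x)
}

#' Plot a comparison report
#'
#' Grouped bars of the balanced F-score per anaphor class for the baseline
#' and the rule-based approach.
#'
#' @param object A `coref_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coref_report <- function(object, ...) {
  t <- filter(object$table, .data$subclass != "global") |>
    mutate(class = paste(.data$category, .data$subclass)) |>
    select("class", baseline = "f_baseline", approach = "f_approach") |>
    tidyr::pivot_longer(c("baseline", "approach"), names_to = "strategy",
                        values_to = "f")
  ggplot2::ggplot(t, ggplot2::aes(x = .data$class, y = .data$f,
                                  fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "balanced F-score", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation
#'
#' Per-class precision, recall and F as grouped bars.
#'
#' @param object An `anaphora_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anaphora_eval <- function(object, ...) {
  t <- object$by_class |>
    mutate(class = paste(.data$category, .data$subclass)) |>
    select("class", "precision", "recall", "f") |>
    tidyr::pivot_longer(c("precision", "recall", "f"), names_to = "metric")
  ggplot2::ggplot(t, ggplot2::aes(x = .data$class, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
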