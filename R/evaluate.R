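# Scoring a scrubbed corpus against gold-standard spans, and the
# potential-breach audit (three or more residual identifiers for one patient
# in a single note, or across that patient's note series).

match_key <- function(x) paste(x$doc_id, x$start, x$end, sep = "\r")

#' Score emitted mask spans against gold-standard spans
#'
#' Spans match by exact offsets on pre-replacement (original text)
#' coordinates. The headline recall is computed over clean-status gold spans
#' only - misspellings and un-entered identifiers are designed misses and
#' are reported separately in the residual table rather than scored as
#' failures. Precision counts every emitted span: one that matches no gold
#' span at all is a false positive. Patient-subject and relative-subject
#' masks are additionally broken out, since the two carry different masking
#' strings.
#'
#' @param emitted Span tibble from the de-identifier (e.g.
#'   `tidy(deidentify(...))`): columns `doc_id`, `start`, `end`, `kind`,
#'   `subject`.
#' @param gold Gold span tibble from [generate_corpus()].
#' @param documents Optional document table ([corpus_documents()]); when
#'   given, the two span sets are checked to refer to the same documents.
#' @return An object of class `deid_eval`.
#' @export
score_spans <- function(emitted, gold, documents = NULL) {
  if (!is.null(documents)) {
    bad <- setdiff(unique(c(emitted$doc_id, gold$doc_id)), documents$doc_id)
    if (length(bad)) {
      abort(paste0("document mismatch: spans refer to unknown doc '", bad[1], "'"))
    }
  }
  gold <- mutate(gold, .matched = match_key(gold) %in% match_key(emitted))
  emitted <- mutate(emitted, .gold = match_key(emitted) %in% match_key(gold))

  clean <- filter(gold, .data$status == "clean")
  tp <- sum(clean$.matched)
  fn <- sum(!clean$.matched)
  fp <- sum(!emitted$.gold)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)

  by_kind <- clean |>
    group_by(.data$kind) |>
    summarise(n_gold = n(), tp = sum(.data$.matched), fn = sum(!.data$.matched),
              recall = ifelse(n() == 0, NA_real_, sum(.data$.matched) / n()),
              .groups = "drop")
  by_subject <- clean |>
    group_by(.data$subject) |>
    summarise(n_gold = n(), tp = sum(.data$.matched), fn = sum(!.data$.matched),
              .groups = "drop")

  residuals <- filter(gold, !.data$.matched) |> select(-".matched")

  structure(
    list(
      n_notes = length(unique(gold$doc_id)),
      n_gold = nrow(clean), tp = tp, fn = fn, fp = fp,
      precision = precision, recall = recall,
      by_kind = by_kind, by_subject = by_subject,
      residuals = residuals,
      n_misspelt = sum(gold$status == "misspelt"),
      n_unentered = sum(gold$status == "unentered")
    ),
    class = "deid_eval"
  )
}

#' @export
print.deid_eval <- function(x, ...) {
  cat("<deid_eval>", x$n_notes, "notes,", x$n_gold, "scoreable identifier spans\n")
  cat(sprintf("  precision %.3f  recall %.3f  (tp %d, fn %d, fp %d)\n",
              x$precision, x$recall, x$tp, x$fn, x$fp))
  cat("  residual identifiers:", nrow(x$residuals),
      sprintf("(%d misspelt, %d un-entered)\n", x$n_misspelt, x$n_unentered))
  invisible(x)
}

#' @describeIn score_spans Per-kind breakdown as a tibble.
#' @param x A `deid_eval`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.deid_eval <- function(x, ...) x$by_kind

#' @describeIn score_spans One-row summary (counts, precision, recall).
#' @exportS3Method generics::glance
glance.deid_eval <- function(x, ...) {
  tibble(n_notes = x$n_notes, n_gold = x$n_gold, tp = x$tp, fn = x$fn, fp = x$fp,
         precision = x$precision, recall = x$recall,
         n_misspelt = x$n_misspelt, n_unentered = x$n_unentered)
}

#' @describeIn score_spans Bar chart of per-kind recall on clean spans.
#' @param object A `deid_eval`.
#' @exportS3Method ggplot2::autoplot
autoplot.deid_eval <- function(object, ...) {
  ggplot(object$by_kind, aes(x = .data$kind, y = .data$recall)) +
    geom_col(fill = "steelblue") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "identifier kind", y = "recall (clean spans)",
         title = "Masking recall by identifier kind") +
    theme_minimal()
}

.residual_labels <- c(
  name = "Patient or contact name", number_date = "Patient date of birth (numeric)",
  word_date = "Patient date of birth (word form)", phone = "Patient contact number",
  nhs_number = "NHS number", trust_id = "Hospital ID number",
  postcode = "Address postcode", address_term = "Address line", word_token = "Name token"
)

#' Residual-identifier table
#'
#' Counts unmasked identifier instances by type, with the reason each class
#' appears in the output (misspelt in source, or never entered in the
#' structured fields). The header row gives the total and the percentage
#' breakdown by reason.
#'
#' @param eval A `deid_eval` from [score_spans()].
#' @return A tibble with columns `pi_type`, `n_instances`, `reason`; the
#'   first row is the overall total. Percentages by reason are attached as
#'   attributes `pct_misspelt` and `pct_unentered`.
#' @export
residual_table <- function(eval) {
  res <- filter(eval$residuals, .data$status %in% c("misspelt", "unentered"))
  total <- nrow(res)
  pct_mis <- if (total == 0) 0 else 100 * sum(res$status == "misspelt") / total
  pct_un <- if (total == 0) 0 else 100 * sum(res$status == "unentered") / total
  body <- res |>
    group_by(.data$kind) |>
    summarise(
      n_instances = n(),
      reason = paste(sort(unique(ifelse(.data$status == "misspelt",
                                        "Misspelling", "Un-entered PI"))),
                     collapse = " or "),
      .groups = "drop"
    ) |>
    arrange(desc(.data$n_instances)) |>
    mutate(pi_type = dplyr::coalesce(unname(.residual_labels[.data$kind]), .data$kind),
           .keep = "unused", .before = 1)
  out <- bind_rows(
    tibble(pi_type = "All residual identifier instances",
           n_instances = total,
           reason = sprintf("%.1f%% due to misspellings; %.1f%% due to PIs being un-entered",
                            pct_mis, pct_un)),
    body
  )
  attr(out, "pct_misspelt") <- pct_mis
  attr(out, "pct_unentered") <- pct_un
  out
}

#' Potential-breach audit
#'
#' Flags any patient with three or more residual (unmasked, true or
#' apparent) identifiers, either within a single note or across the
#' patient's note series. Duplicate mentions of the same residual value
#' count once per note: the rule concerns distinct identifying facts.
#'
#' @param residuals Residual-span tibble (e.g. `score_spans(...)$residuals`):
#'   columns `patient_id`, `doc_id`, `kind`, `status`, `surface`.
#' @param window `"single_note"` or `"note_series"`.
#' @param threshold Number of residual identifiers constituting a potential
#'   breach (default 3).
#' @return A tibble of findings: `patient_id`, `window`, `n_instances`, and
#'   a list column `instances` of the contributing (kind, status, doc_id)
#'   rows.
#' @export
audit_breaches <- function(residuals, window = c("single_note", "note_series"),
                           threshold = 3) {
  window <- match.arg(window)
  if (nrow(residuals) == 0) {
    return(tibble(patient_id = character(), window = character(),
                  n_instances = integer(), instances = list()))
  }
  # one vote per distinct value per note (surface may be absent when reading
  # back a standoff table that deliberately omits matched text)
  keys <- intersect(c("patient_id", "doc_id", "kind", "status", "surface"),
                    names(residuals))
  res <- distinct(residuals[, keys])
  grouped <- if (window == "single_note") {
    group_by(res, .data$patient_id, .data$doc_id)
  } else {
    group_by(res, .data$patient_id)
  }
  grouped |>
    filter(n() >= threshold) |>
    summarise(n_instances = n(),
              instances = list(pick(dplyr::everything())),
              .groups = "drop") |>
    mutate(window = window) |>
    select("patient_id", "window", "n_instances", "instances")
}

#' End-to-end evaluation of the de-identifier on a corpus
#'
#' Convenience wrapper: de-identifies `records`, scores the emitted spans
#' against `gold`, and runs the breach audit in both window modes.
#'
#' @param records Corpus tibble.
#' @param gold Gold spans from [generate_corpus()].
#' @param policy,config See [deidentify()].
#' @return A list: `deid` (`deid_corpus`), `eval` (`deid_eval`),
#'   `breaches_single_note`, `breaches_note_series`.
#' @export
evaluate_corpus <- function(records, gold, policy = default_field_policy(),
                            config = scrub_config()) {
  deid <- deidentify(records, policy = policy, config = config)
  ev <- score_spans(deid$spans, gold, documents = corpus_documents(records))
  list(
    deid = deid,
    eval = ev,
    breaches_single_note = audit_breaches(ev$residuals, "single_note"),
    breaches_note_series = audit_breaches(ev$residuals, "note_series")
  )
}
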