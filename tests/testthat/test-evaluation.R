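mk_gold <- function(n, doc = "d1", status = "clean", kind = "name") {
  tibble::tibble(
    patient_id = "p", doc_id = doc, start = seq_len(n) * 10L,
    end = seq_len(n) * 10L + 4L, kind = kind, subject = "patient",
    status = status, surface = paste0("s", seq_len(n))
  )
}

as_emitted <- function(gold) {
  tibble::tibble(patient_id = gold$patient_id, doc_id = gold$doc_id,
                 start = gold$start, end = gold$end, kind = gold$kind,
                 subject = gold$subject, replacement = "ZZZZZ")
}

test_that("precision and recall follow their definitions on fixed counts", {
  gold <- mk_gold(10)
  # 8 of 10 masked, no spurious masks
  ev <- score_spans(as_emitted(gold[1:8, ]), gold)
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$recall, 0.8)
  expect_identical(c(ev$tp, ev$fn, ev$fp), c(8L, 2L, 0L))

  # all masked plus 2 spurious
  spurious <- as_emitted(mk_gold(2))
  spurious$start <- spurious$start + 1000L
  spurious$end <- spurious$end + 1000L
  ev2 <- score_spans(dplyr::bind_rows(as_emitted(gold), spurious), gold)
  expect_equal(ev2$precision, 10 / 12)
  expect_equal(ev2$recall, 1.0)
  g <- glance(ev2)
  expect_identical(c(g$tp, g$fn, g$fp), c(10L, 0L, 2L))
})

test_that("non-clean gold spans are excluded from the headline metrics", {
  gold <- dplyr::bind_rows(mk_gold(6), mk_gold(4, doc = "d2", status = "misspelt"))
  ev <- score_spans(as_emitted(gold[gold$status == "clean", ]), gold)
  expect_equal(ev$recall, 1.0)
  expect_identical(ev$n_gold, 6L)
  expect_identical(ev$n_misspelt, 4L)
  expect_identical(nrow(ev$residuals), 4L)
})

test_that("scoring equals a brute-force set comparison on random corpora", {
  withr::local_seed(31)
  for (case in 1:10) {
    gold <- mk_gold(sample(5:30, 1))
    gold$status <- sample(c("clean", "misspelt", "unentered"), nrow(gold),
                          replace = TRUE, prob = c(0.7, 0.2, 0.1))
    hit <- runif(nrow(gold)) < 0.8
    emitted <- as_emitted(gold[hit & gold$status == "clean", ])
    n_spur <- sample(0:3, 1)
    if (n_spur > 0) {
      sp <- as_emitted(mk_gold(n_spur))
      sp$start <- sp$start + 5000L; sp$end <- sp$end + 5000L
      emitted <- dplyr::bind_rows(emitted, sp)
    }
    ev <- score_spans(emitted, gold)
    # brute force: compare key sets directly
    gk <- paste(gold$doc_id, gold$start, gold$end)
    ek <- paste(emitted$doc_id, emitted$start, emitted$end)
    clean_k <- gk[gold$status == "clean"]
    expect_identical(ev$tp, length(intersect(clean_k, ek)))
    expect_identical(ev$fn, length(setdiff(clean_k, ek)))
    expect_identical(ev$fp, sum(!ek %in% gk))
  }
})

test_that("document mismatch between span sets is an error", {
  gold <- mk_gold(2)
  docs <- tibble::tibble(patient_id = "p", doc_id = "other",
                         scope_id = "event_note", date = as.Date(NA), text = "t")
  expect_error(score_spans(as_emitted(gold), gold, documents = docs),
               "document mismatch")
})

residuals_of <- function(items) {
  tibble::tibble(
    patient_id = "p1",
    doc_id = vapply(items, `[[`, "", "doc"),
    kind = vapply(items, `[[`, "", "kind"),
    status = "misspelt",
    surface = vapply(items, `[[`, "", "surface")
  )
}

test_that("three residual identifiers in one note raise one breach finding", {
  # misspelt address line + postcode + last name, all in the same note
  res <- residuals_of(list(
    list(doc = "n1", kind = "address_term", surface = "3 hazlemere lne"),
    list(doc = "n1", kind = "postcode", surface = "en1 5rs"),
    list(doc = "n1", kind = "name", surface = "blogs")
  ))
  f <- audit_breaches(res, "single_note")
  expect_identical(nrow(f), 1L)
  expect_identical(f$n_instances, 3L)
  # two residuals: below threshold
  expect_identical(nrow(audit_breaches(res[1:2, ], "single_note")), 0L)
})

test_that("instances spread over notes only count in note-series mode", {
  res <- residuals_of(list(
    list(doc = "n1", kind = "name", surface = "blogs"),
    list(doc = "n2", kind = "postcode", surface = "en1 5rs"),
    list(doc = "n3", kind = "number_date", surface = "01/01/2010")
  ))
  expect_identical(nrow(audit_breaches(res, "single_note")), 0L)
  expect_identical(nrow(audit_breaches(res, "note_series")), 1L)
})

test_that("duplicate mentions of one value count once per note", {
  res <- residuals_of(list(
    list(doc = "n1", kind = "name", surface = "blogs"),
    list(doc = "n1", kind = "name", surface = "blogs"),
    list(doc = "n1", kind = "name", surface = "blogs")
  ))
  expect_identical(nrow(audit_breaches(res, "single_note")), 0L)
})

test_that("adding a residual instance never removes a finding", {
  res <- residuals_of(list(
    list(doc = "n1", kind = "name", surface = "a"),
    list(doc = "n1", kind = "postcode", surface = "b"),
    list(doc = "n1", kind = "phone", surface = "c")
  ))
  base <- audit_breaches(res, "single_note")
  more <- dplyr::bind_rows(res, residuals_of(list(
    list(doc = "n1", kind = "nhs_number", surface = "d")
  )))
  grown <- audit_breaches(more, "single_note")
  expect_true(all(base$patient_id %in% grown$patient_id))
  expect_gte(grown$n_instances[1], base$n_instances[1])
})

test_that("residual table mirrors the published layout", {
  gold <- dplyr::bind_rows(
    mk_gold(3, status = "misspelt", kind = "name"),
    mk_gold(1, doc = "d2", status = "unentered", kind = "name"),
    mk_gold(2, doc = "d3", status = "misspelt", kind = "postcode")
  )
  ev <- score_spans(as_emitted(gold[0, ]), gold)
  tab <- residual_table(ev)
  expect_identical(tab$n_instances[1], 6L)
  expect_match(tab$reason[1], "misspellings")
  expect_identical(tab$pi_type[tab$n_instances == 4 & tab$pi_type != tab$pi_type[1]],
                   "Patient or contact name")
  expect_match(tab$reason[tab$pi_type == "Patient or contact name"],
               "Misspelling or Un-entered PI")
  expect_equal(attr(tab, "pct_misspelt"), 100 * 5 / 6, tolerance = 1e-10)
})

test_that("tidy, glance and autoplot methods expose the evaluation", {
  gc <- generate_corpus(4, corruption_profile(seed = 2))
  ev <- evaluate_corpus(gc$records, gc$gold)
  expect_s3_class(tidy(ev$eval), "tbl_df")
  expect_true(all(c("kind", "recall") %in% names(tidy(ev$eval))))
  expect_identical(nrow(glance(ev$eval)), 1L)
  p <- ggplot2::autoplot(ev$eval)
  expect_s3_class(p, "ggplot")
  expect_s3_class(tidy(ev$deid), "tbl_df")
  expect_s3_class(glance(ev$deid), "tbl_df")
  expect_s3_class(tidy(build_dictionary(gc$records[1, ])), "tbl_df")
})
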