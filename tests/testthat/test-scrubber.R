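test_that("token boundaries follow the prefix/suffix character rules", {
  # prefix: non-alphanumeric or start of text; suffix: non-alphanumeric,
  # sentence punctuation, or end of text
  expect_true(token_boundaries("7)Mark is", 2, 6))
  expect_false(token_boundaries("OMark is", 1, 5))
  expect_true(token_boundaries("Mark", 0, 4))          # whole text
  expect_true(token_boundaries("Mark.", 0, 4))         # sentence punctuation
  expect_true(token_boundaries("x Mark;y", 2, 6))
  expect_false(token_boundaries("Marky", 0, 4))        # letter suffix
  expect_false(token_boundaries("9Mark ", 1, 5))       # digit prefix
  expect_true(token_boundaries("\nMark ", 1, 5))       # line start
})

name_rows <- list(
  list("...replaced. Mark will also be able...", "...replaced. ZZZZZ will also be able..."),
  list("...knowing Mark’s diagnosis...", "...knowing ZZZZZ diagnosis..."),
  list("...7)Mark is compliant...", "...7)ZZZZZ is compliant..."),
  list("...OMark is compliant...", "...OMark is compliant..."),
  list("...was awarded 9 mark out of 30 in...", "...was awarded 9 ZZZZZ out of 30 in..."),
  list("...Nurse informed Mark. Earlier...", "...Nurse informed ZZZZZ. Earlier..."),
  list("...Marik will be attending...", "...Marik will be attending..."),
  list("...O’Mark is at the...", "...ZZZZZ is at the..."),
  list("...his father, John, was also present...", "...his father, QQQQQ, was also present...")
)

test_that("name heuristics reproduce the documented behaviours", {
  dict <- build_dictionary(mark_record())
  for (row in name_rows) {
    expect_identical(scrub_text(row[[1]], dict)$text, row[[2]])
  }
  # straight-apostrophe dialect behaves the same
  expect_identical(scrub_text("knowing Mark's diagnosis", dict)$text,
                   "knowing ZZZZZ diagnosis")
  expect_identical(scrub_text("O'Mark is at the door", dict)$text,
                   "ZZZZZ is at the door")
})

date_rows <- list(
  list("Dob: 01/01/2001", "Dob: ZZZZZ"),
  list("1st of January 2001", "ZZZZZ"),
  list("...born in Jan 1st 01...", "...born in ZZZZZ..."),
  list("...01-01-’01...", "...ZZZZZ..."),
  list("...01 Jan 2001...", "...ZZZZZ..."),
  list("Dob: 01//01/2001", "Dob: 01//01/2001")
)

test_that("date-of-birth heuristics reproduce the documented behaviours", {
  dict <- build_dictionary(dob_2001_record())
  for (row in date_rows) {
    expect_identical(scrub_text(row[[1]], dict)$text, row[[2]])
  }
  # a different date never matches
  expect_identical(scrub_text("03/04/2001", dict)$text, "03/04/2001")
  # superscript ordinal markers accepted
  expect_identical(scrub_text("1^st^ of January 2001", dict)$text, "ZZZZZ")
  # two-digit years resolve by century proximity to the birth year
  expect_identical(scrub_text("dob 01/01/01.", dict)$text, "dob ZZZZZ.")
})

test_that("postcode heuristics mask only the exact source postcode", {
  dict <- build_dictionary(en1_record())
  expect_identical(scrub_text("He lives at EN1 5SR", dict)$text, "He lives at ZZZZZ")
  expect_identical(scrub_text("Lives at EN1. No...", dict)$text, "Lives at EN1. No...")
  expect_identical(scrub_text("Lives at EN1 S5R", dict)$text, "Lives at EN1 S5R")
  expect_identical(scrub_text("code en15sr here", dict)$text, "code ZZZZZ here")
})

test_that("phone and ID heuristics match on normalized digits", {
  rec <- source_record("ph", "Jo", "Kim", trust_id = "12-34-56",
                       phone_numbers = "00000000000", nhs_number = "9434765919")
  dict <- build_dictionary(rec)
  expect_identical(scrub_text("call 12 34 56 re appt", dict)$text,
                   "call ZZZZZ re appt")
  expect_identical(scrub_text("(00000) 000 000", dict)$text, "ZZZZZ")
  expect_identical(scrub_text("ward extension 4567", dict)$text,
                   "ward extension 4567")
  expect_identical(scrub_text("nhs 943 476 5919;", dict)$text, "nhs ZZZZZ;")
  expect_identical(scrub_text("id 12–34–56 held", dict)$text,
                   "id ZZZZZ held")
})

test_that("address runs of two or more terms are masked as one span", {
  rec <- source_record("ad", "Ann", "Lee",
                       addresses = address("12 Acacia Road", postcode = "SW9 6TJ"))
  dict <- build_dictionary(rec)
  expect_identical(scrub_text("moved to 12 Acacia Rd last week", dict)$text,
                   "moved to ZZZZZ last week")
  expect_identical(scrub_text("walked down the road", dict)$text,
                   "walked down the road")
  expect_identical(scrub_text("Acacia Road, SW9", dict)$text, "ZZZZZ, SW9")
  # a bare house number is not evidence on its own
  expect_identical(scrub_text("scored 12 points", dict)$text, "scored 12 points")
})

test_that("overlap resolution keeps the longest span and masks locally", {
  spans <- tibble::tibble(
    start = c(0L, 0L, 8L), end = c(6L, 13L, 13L),
    kind = c("name", "address_term", "name"),
    subject = c("patient", "patient", "relative")
  )
  res <- resolve_spans(spans)
  expect_identical(nrow(res), 1L)
  expect_identical(res$end - res$start, 13L)
  expect_identical(res$replacement, "ZZZZZ")
  # no spans: identity
  expect_identical(mask_text("abc", resolve_spans(tibble::tibble(
    start = integer(), end = integer(), kind = character(), subject = character()
  ))), "abc")
  # out-of-range span is an internal error
  expect_error(mask_text("ab", tibble::tibble(start = 0L, end = 9L, kind = "name",
                                              subject = "patient",
                                              replacement = "ZZZZZ")),
               "internal error")
})

test_that("scrubbing is idempotent and local", {
  dict <- build_dictionary(joe_bloggs_record())
  texts <- c(
    "Joe Bloggs attended on 20/08/1987, SW9 6TJ, id 12 34 56.",
    "Discussed Bloggs's plan with O'Connell's family.",
    "nothing identifying here at all"
  )
  for (t in texts) {
    once <- scrub_text(t, dict)$text
    twice <- scrub_text(once, dict)$text
    expect_identical(twice, once)
  }
  # locality: the masked text is exactly the original with each resolved
  # span substituted, everything else byte-identical
  res <- scrub_text(texts[1], dict)
  sp <- res$spans
  expect_true(nrow(sp) >= 3)
  rebuilt <- ""
  pos <- 0L
  for (i in seq_len(nrow(sp))) {
    rebuilt <- paste0(rebuilt, substr(texts[1], pos + 1, sp$start[i]), sp$replacement[i])
    pos <- sp$end[i]
  }
  rebuilt <- paste0(rebuilt, substr(texts[1], pos + 1, nchar(texts[1])))
  expect_identical(res$text, rebuilt)
})

test_that("soundness: no dictionary literal survives at a valid boundary", {
  dict <- build_dictionary(joe_bloggs_record())
  txt <- paste(
    "Joe Bloggs, dob 20.08.87 (also written 20th of August 1987), SW96TJ,",
    "trust 123456, contact Connell."
  )
  masked <- scrub_text(txt, dict)$text
  expect_false(identical(masked, txt))
  low <- tolower(masked)
  for (surf in dict$entries$surface) {
    hit <- stringi::stri_locate_all_fixed(low, surf)[[1]]
    if (is.na(hit[1, 1])) next
    ok <- token_boundaries(masked, hit[, 1] - 1, hit[, 2])
    expect_false(any(ok), info = surf)
  }
})

test_that("scanner spans agree with the brute-force all-substring oracle", {
  withr::local_seed(404)
  for (case in 1:60) {
    n_entries <- sample(3:20, 1)
    entries <- unique(replicate(n_entries, paste(
      sample(letters[1:10], sample(2:6, 1), replace = TRUE), collapse = ""
    )))
    subjects <- sample(c("patient", "relative"), length(entries), replace = TRUE)
    dict <- name_only_dict(entries, subjects)
    txt <- random_name_text(entries, max_len = 300)
    got <- sorted_spans(scan_names(txt, dict))
    want <- sorted_spans(brute_name_spans(txt, dict$entries))
    expect_identical(got, want, info = paste("case", case))
  }
})
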