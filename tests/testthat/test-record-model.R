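test_that("XML round-trip is the identity on a fully populated record", {
  docs <- dplyr::bind_rows(
    document("d1", "event_note", "Line one.\n  Indented line with trailing spaces.  ",
             date = "2012-04-02"),
    document("d2", "correspondence", "Contains <angle> & ampersand 'quotes'.")
  )
  rec <- source_record(
    "p1", "Joe", "Bloggs", middle_name = "James", nickname = "JJ",
    date_of_birth = "1987-08-20", nhs_number = "9434765919", trust_id = "12-34-56",
    phone_numbers = c("07123456789", "02071234567"),
    addresses = dplyr::bind_rows(
      address("12 Acacia Road", line2 = "Brixton", postcode = "SW9 6TJ"),
      address("3 Old Lane", postcode = "EN1 5SR", status = "old")
    ),
    key_contacts = tibble::tibble(first_name = "Mary", last_name = "O'Connell"),
    documents = docs
  )
  path <- withr::local_tempfile(fileext = ".xml")
  write_corpus_xml(rec, path)
  back <- read_corpus_xml(path)
  expect_equal(back, rec)
  # text offsets stable: byte-identical document text
  expect_identical(back$documents[[1]]$text, docs$text)

  # single-patient writer/reader agree too
  p2 <- withr::local_tempfile(fileext = ".xml")
  write_record(rec, p2)
  expect_equal(read_record(p2), rec)
})

test_that("absent fields read back as absent, never as empty strings", {
  xml <- '<patient id="p9"><identifiers><first_name>Ann</first_name><last_name>Lee</last_name></identifiers></patient>'
  rec <- read_record(xml)
  expect_identical(rec$middle_name, NA_character_)
  expect_identical(rec$nhs_number, NA_character_)
  expect_true(is.na(rec$date_of_birth))
  expect_identical(rec$phone_numbers[[1]], character(0))
  expect_identical(nrow(rec$documents[[1]]), 0L)

  # a stripped field is absent from serialized output entirely
  out <- write_record(rec)
  expect_false(grepl("nhs_number", out, fixed = TRUE))
  expect_false(grepl("middle_name", out, fixed = TRUE))
})

test_that("malformed XML and unknown elements raise informative errors", {
  expect_error(read_record("<patient id='x'><identifiers>"), regexp = ".")
  expect_error(
    read_record('<patient id="x"><mystery/></patient>'),
    "schema error"
  )
  expect_error(
    read_record('<patient id="x"><identifiers><shoe_size>9</shoe_size></identifiers></patient>'),
    "schema error"
  )
  expect_error(read_corpus_xml("<records/>"), "schema error")
})

test_that("JSONL round-trip is the identity on generated records", {
  gc <- generate_corpus(4, corruption_profile(0.2, 0.1, seed = 11))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(gc$records, path)
  expect_equal(read_corpus_jsonl(path), gc$records)
})

test_that("XML round-trip is the identity on generated records", {
  gc <- generate_corpus(5, corruption_profile(0.3, 0.1, seed = 23))
  path <- withr::local_tempfile(fileext = ".xml")
  write_corpus_xml(gc$records, path)
  expect_equal(read_corpus_xml(path), gc$records)
})

test_that("corpus invariants are enforced", {
  rec <- source_record("dup", "Ann", "Lee")
  expect_error(assertable <- read_corpus_jsonl(textConnection("")), NA)
  expect_error(write_corpus_xml(dplyr::bind_rows(rec, rec)), "unique")
  expect_error(source_record("", "Ann", "Lee"), "patient_id")
  expect_error(source_record("p", NA, "Lee"), "mandatory")
  expect_error(source_record("p", "Ann", ""), "mandatory")
})
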