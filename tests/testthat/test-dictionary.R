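test_that("name delimiters are stripped and 1-char fragments dropped", {
  expect_identical(strip_name_delimiters("O'Connell"), "Connell")
  expect_identical(strip_name_delimiters("Smith"), "Smith")
  expect_identical(strip_name_delimiters("Jean-Paul"), c("Jean", "Paul"))
  expect_identical(strip_name_delimiters("D’Souza"), "Souza")  # curly apostrophe
  expect_identical(strip_name_delimiters(NA), character())
})

test_that("date-of-birth expansion covers the documented variant shapes", {
  v <- expand_date_variants(as.Date("1987-08-20"))
  expect_true(all(c(
    "20/08/1987", "20/08/'87", "20-08-1987", "20-08-87",
    "20.08.1987", "20.08.87", "20.8.87",
    "20th Aug 1987", "20th Aug '87", "20th of August 1987", "20th of Aug 1987"
  ) %in% v))
  v2 <- expand_date_variants(as.Date("2001-01-01"))
  expect_true(all(c("01/01/2001", "1st of January 2001") %in% v2))
  expect_true("1.1.01" %in% v2)  # un-padded dot form
  expect_identical(expand_date_variants(as.Date(NA)), character())
})

test_that("every emitted date variant is recognised by the date scanners", {
  dates <- as.Date(c("1987-08-20", "2001-01-01", "1944-12-03", "1999-02-28",
                     "1960-10-31", "2003-07-04"))
  for (i in seq_along(dates)) {
    dob <- dates[i]
    rec <- source_record("rt", "Ann", "Lee", date_of_birth = dob)
    dict <- build_dictionary(rec)
    for (v in expand_date_variants(dob)) {
      masked <- scrub_text(paste0("dob ", v, " noted"), dict)$text
      expect_identical(masked, "dob ZZZZZ noted")
    }
  }
})

test_that("ID numbers expand to as-entered, digits-only and spaced forms", {
  expect_setequal(expand_id_variants("12–34–56"),   # en-dashes
                  c("12-34-56", "123456", "12 34 56"))
  expect_identical(expand_id_variants("123456"), "123456")
  expect_setequal(expand_id_variants("12-3456"), c("12-3456", "123456", "12 3456"))
  expect_identical(expand_id_variants("no-digits"), character())
})

test_that("postcodes expand to spaced and unspaced forms, case-normalized", {
  expect_setequal(expand_postcode_variants("SW9 6TJ"), c("SW9 6TJ", "SW96TJ"))
  expect_setequal(expand_postcode_variants("EN1 5SR"), c("EN1 5SR", "EN15SR"))
  expect_setequal(expand_postcode_variants("sw96tj"), c("SW9 6TJ", "SW96TJ"))
  # malformed input stays a single literal
  expect_identical(expand_postcode_variants("XYZ"), "XYZ")
})

test_that("phone numbers expand to the three UK groupings with brackets", {
  v <- expand_phone_variants("00000000000")
  expect_true(all(c("00000000000", "00000 000 000") %in% v))
  expect_true("(020) 7123 4567" %in% expand_phone_variants("02071234567"))
  expect_identical(expand_phone_variants("123456789"), "123456789")  # 9 digits
})

test_that("address lines expand to alias-closed term sets", {
  tt <- expand_address_terms(address("12 Acacia Road"))
  expect_true(all(c("12", "acacia", "road", "rd") %in% tt$term))
  expect_true(tt$is_number[tt$term == "12"])
  expect_identical(nrow(expand_address_terms(address())), 0L)
  tt2 <- expand_address_terms(address("1 High Street"))
  expect_true(all(c("st", "street", "1") %in% tt2$term))
})

test_that("the worked-example fields build the full 19-entry dictionary", {
  dict <- build_dictionary(joe_bloggs_record())
  expect_true(all(joe_bloggs_expected_entries() %in% dict$entries$surface))
  # the only addition beyond the documented 19 is the bare 2-digit slash year
  expect_setequal(setdiff(dict$entries$surface, joe_bloggs_expected_entries()),
                  "20/08/87")
  expect_identical(
    dict$entries$subject[dict$entries$surface == "connell"], "relative"
  )
  expect_false(any(duplicated(dict$entries)))
})

test_that("a minimal record yields exactly its two name tokens", {
  dict <- build_dictionary(source_record("m", "Ann", "Lee"))
  expect_setequal(dict$entries$surface, c("ann", "lee"))
  expect_true(all(dict$entries$kind == "name"))
})

test_that("dictionary building is monotone in added fields", {
  base <- source_record("m", "Ann", "Lee")
  fuller <- source_record("m", "Ann", "Lee", nickname = "Nell",
                          trust_id = "77-88-99",
                          addresses = address("4 Foxglove Close", postcode = "SE5 8AW"))
  e1 <- build_dictionary(base)$entries
  e2 <- build_dictionary(fuller)$entries
  expect_true(all(e1$surface %in% e2$surface))
  expect_gt(nrow(e2), nrow(e1))
})

test_that("dictionary dump/load round-trips", {
  dict <- build_dictionary(joe_bloggs_record())
  path <- withr::local_tempfile(fileext = ".json")
  dump_dictionary(dict, path)
  back <- load_dictionary(path)
  expect_setequal(back$entries$surface, dict$entries$surface)
  expect_identical(back$canonical_dob, dict$canonical_dob)
  expect_identical(back$canonical_postcodes, dict$canonical_postcodes)
})
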