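# Fixture builders shared across tests. All values are fictitious.

# The worked-example patient: Joe Bloggs, DOB 20/08/1987, Trust ID 12-34-56,
# postcode SW9 6TJ, key contact O'Connell.
joe_bloggs_record <- function(documents = NULL) {
  rec <- source_record(
    patient_id = "JB01",
    first_name = "Joe", last_name = "Bloggs",
    date_of_birth = "1987-08-20",
    trust_id = "12-34-56",
    addresses = address(postcode = "SW9 6TJ"),
    key_contacts = tibble::tibble(first_name = NA_character_, last_name = "O'Connell")
  )
  if (!is.null(documents)) rec$documents <- list(documents)
  rec
}

# The 19 dictionary strings the Joe Bloggs fields must expand to
# (ASCII-punctuation dialect, lowercase as stored).
joe_bloggs_expected_entries <- function() {
  tolower(c(
    "Joe", "Bloggs",
    "20/08/1987", "20/08/'87", "20-08-1987", "20-08-87",
    "20.08.1987", "20.08.87", "20.8.87",
    "20th Aug 1987", "20th Aug '87", "20th of August 1987", "20th of Aug 1987",
    "12-34-56", "123456", "12 34 56",
    "SW9 6TJ", "SW96TJ",
    "Connell"
  ))
}

# Patient whose dictionary holds name Mark (patient) and John (relative),
# used for the name-heuristic worked examples.
mark_record <- function() {
  source_record(
    patient_id = "MK01", first_name = "Mark", last_name = "Dunn",
    key_contacts = tibble::tibble(first_name = "John", last_name = "Field")
  )
}

dob_2001_record <- function() {
  source_record(patient_id = "DB01", first_name = "Ann", last_name = "Lee",
                date_of_birth = "2001-01-01")
}

en1_record <- function() {
  source_record(patient_id = "PC01", first_name = "Ann", last_name = "Lee",
                addresses = address(postcode = "EN1 5SR"))
}

scrub1 <- function(text, record, ...) {
  scrub_text(text, build_dictionary(record), ...)$text
}
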