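# Patient record model: one row per patient, nested tibbles for addresses,
# key contacts and documents. Empty strings are normalized to NA ("absent"):
# a blank structured field contributes nothing to the cleaning dictionary.

chr_or_na <- function(x) {
  x <- as.character(x %||% NA_character_)
  if (length(x) == 0) x <- NA_character_
  x <- x[1]
  if (is.na(x) || stri_trim_both(x) == "") NA_character_ else x
}

#' Construct an address
#'
#' @param line1,line2,line3 Address lines (or `NA` when absent).
#' @param postcode UK-style postcode, outward + inward parts with optional
#'   space (or `NA`).
#' @param status `"current"` or `"old"`.
#' @return A one-row tibble.
#' @export
#' @examples
#' address("12 Acacia Road", postcode = "SW9 6TJ")
address <- function(line1 = NA, line2 = NA, line3 = NA, postcode = NA,
                    status = c("current", "old")) {
  status <- match.arg(status)
  tibble(
    line1 = chr_or_na(line1), line2 = chr_or_na(line2), line3 = chr_or_na(line3),
    postcode = chr_or_na(postcode), status = status
  )
}

#' Construct a free-text document assigned to a scope
#'
#' @param doc_id Opaque document identifier.
#' @param scope_id Name of the scope (XML tag) the document belongs to; only
#'   documents in configured scopes are scrubbed.
#' @param text Free text. Character offsets into it are 0-based, half-open.
#' @param date Document date (`Date` or `"YYYY-MM-DD"`), or `NA`.
#' @return A one-row tibble.
#' @export
document <- function(doc_id, scope_id, text, date = NA) {
  stopifnot(is.character(text), length(text) == 1)
  tibble(
    doc_id = as.character(doc_id),
    scope_id = as.character(scope_id),
    date = as_date_or_na(date),
    text = text
  )
}

as_date_or_na <- function(x) {
  if (length(x) == 0 || is.null(x)) return(as.Date(NA))
  if (inherits(x, "Date")) return(x[1])
  x <- chr_or_na(x)
  if (is.na(x)) return(as.Date(NA))
  d <- as.Date(x, format = "%Y-%m-%d")
  if (is.na(d)) abort(paste0("invalid date: '", x, "' (expected YYYY-MM-DD)"))
  d
}

empty_addresses <- function() address()[0, ]
empty_contacts <- function() tibble(first_name = character(), last_name = character())
empty_documents <- function() {
  tibble(doc_id = character(), scope_id = character(),
         date = as.Date(character()), text = character())
}

#' Construct a patient source record
#'
#' One row describes one patient: the structured identifier fields the
#' cleaning dictionary is built from, plus the scoped free-text documents the
#' scrubber runs over. First and last name are mandatory (they are mandatory
#' in the source system); every other identifier field may be absent.
#'
#' @param patient_id Opaque, non-empty patient identifier.
#' @param first_name,last_name Mandatory name fields.
#' @param middle_name,nickname Optional name fields (`NA` when absent).
#' @param date_of_birth `Date` or `"YYYY-MM-DD"`, or `NA`.
#' @param nhs_number Digit string, optionally delimited, or `NA`.
#' @param trust_id Delimited digit string (hospital-specific ID), or `NA`.
#' @param phone_numbers Character vector of 10-11 digit UK-style numbers.
#' @param addresses Tibble of [address()] rows.
#' @param key_contacts Tibble with columns `first_name`, `last_name`
#'   (relative / close-contact names, masked with QQQQQ downstream).
#' @param documents Tibble of [document()] rows.
#' @return A one-row tibble with list columns for the repeated fields; bind
#'   rows of these to form a corpus.
#' @export
#' @examples
#' source_record("p1", "Joe", "Bloggs", date_of_birth = "1987-08-20")
source_record <- function(patient_id, first_name, last_name,
                          middle_name = NA, nickname = NA,
                          date_of_birth = NA, nhs_number = NA, trust_id = NA,
                          phone_numbers = character(),
                          addresses = empty_addresses(),
                          key_contacts = empty_contacts(),
                          documents = empty_documents()) {
  patient_id <- chr_or_na(patient_id)
  first_name <- chr_or_na(first_name)
  last_name <- chr_or_na(last_name)
  if (is.na(patient_id)) abort("patient_id must be non-empty")
  if (is.na(first_name) || is.na(last_name)) {
    abort("first_name and last_name are mandatory fields")
  }
  phone_numbers <- as.character(phone_numbers)
  phone_numbers <- phone_numbers[!is.na(phone_numbers) & phone_numbers != ""]
  tibble(
    patient_id = patient_id,
    first_name = first_name,
    middle_name = chr_or_na(middle_name),
    last_name = last_name,
    nickname = chr_or_na(nickname),
    date_of_birth = as_date_or_na(date_of_birth),
    nhs_number = chr_or_na(nhs_number),
    trust_id = chr_or_na(trust_id),
    phone_numbers = list(phone_numbers),
    addresses = list(as_tibble(addresses)),
    key_contacts = list(as_tibble(key_contacts)),
    documents = list(as_tibble(documents))
  )
}

# Column order / presence check used by readers and the pipeline.
assert_corpus <- function(records) {
  needed <- c("patient_id", "first_name", "middle_name", "last_name", "nickname",
              "date_of_birth", "nhs_number", "trust_id", "phone_numbers",
              "addresses", "key_contacts", "documents")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort(paste0("corpus is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(records$patient_id)) {
    abort("patient_id must be unique within a corpus")
  }
  invisible(records)
}

#' Extract the document table of a corpus
#'
#' @param records A corpus tibble (rows from [source_record()]).
#' @return A tibble with one row per document: `patient_id`, `doc_id`,
#'   `scope_id`, `date`, `text`.
#' @export
corpus_documents <- function(records) {
  records |>
    select("patient_id", "documents") |>
    unnest("documents")
}
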