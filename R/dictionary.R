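# Per-patient cleaning dictionary. Every structured identifier is expanded
# into the surface variants the scanners recognise; literal entries are stored
# lowercase and in the ASCII punctuation dialect so matching is
# case-insensitive and hyphen/apostrophe-dialect-independent.

#' Split a name into dictionary tokens
#'
#' Names are stripped of delimiters (apostrophes, hyphens, whitespace) before
#' entering the dictionary. Single-character fragments produced by the split
#' (e.g. the "O" of "O'Connell") are dropped: one-letter entries would mask
#' vast amounts of ordinary text.
#'
#' @param name Name text.
#' @return Character vector of name tokens (original case).
#' @export
#' @examples
#' strip_name_delimiters("O'Connell")  # "Connell"
#' strip_name_delimiters("Jean-Paul")  # "Jean" "Paul"
strip_name_delimiters <- function(name) {
  if (length(name) == 0 || is.na(name)) return(character())
  parts <- unlist(stri_split_regex(
    name,
    paste0("[\\s\\-", paste(c(.apostrophes, setdiff(.dashes, "-")), collapse = ""), "]+")
  ))
  parts[stri_length(parts) >= 2]
}

#' Expand a date of birth into its recognised written variants
#'
#' Emits the closed set of surface shapes the scrubber understands: slash,
#' hyphen and dot numeric forms with 4-digit, 2-digit and apostrophe-2-digit
#' years (dot forms also un-padded), and ordinal word forms with abbreviated
#' and full month names ("20th Aug 1987", "20th of August 1987").
#'
#' @param dob A `Date`.
#' @return Character vector of variant strings.
#' @export
#' @examples
#' expand_date_variants(as.Date("1987-08-20"))
expand_date_variants <- function(dob) {
  if (length(dob) == 0 || is.na(dob)) return(character())
  d <- as.integer(format(dob, "%d"))
  m <- as.integer(format(dob, "%m"))
  y <- as.integer(format(dob, "%Y"))
  dd <- sprintf("%02d", d); mm <- sprintf("%02d", m)
  yyyy <- sprintf("%04d", y); yy <- sprintf("%02d", y %% 100)
  mon <- .month_table$abbrev[m]; month <- .month_table$full[m]
  ord <- paste0(d, ordinal_suffix(d))
  unique(c(
    paste0(dd, "/", mm, "/", yyyy),
    paste0(dd, "/", mm, "/'", yy),
    paste0(dd, "/", mm, "/", yy),
    paste0(dd, "-", mm, "-", yyyy),
    paste0(dd, "-", mm, "-", yy),
    paste0(dd, ".", mm, ".", yyyy),
    paste0(dd, ".", mm, ".", yy),
    paste0(d, ".", m, ".", yy),
    paste(ord, mon, yyyy),
    paste0(ord, " ", mon, " '", yy),
    paste(ord, "of", month, yyyy),
    paste(ord, "of", mon, yyyy)
  ))
}

#' Expand a delimited ID number into its variants
#'
#' The as-entered form (punctuation-normalized), the digits-only form, and a
#' space-delimited form preserving the original digit grouping.
#'
#' @param id_string Digits with optional delimiters.
#' @return Character vector of variants; empty when the input carries no
#'   digits.
#' @export
#' @examples
#' expand_id_variants("12-34-56")  # "12-34-56" "123456" "12 34 56"
expand_id_variants <- function(id_string) {
  if (length(id_string) == 0 || is.na(id_string)) return(character())
  groups <- unlist(stri_extract_all_regex(id_string, "\\d+"))
  groups <- groups[!is.na(groups)]
  if (length(groups) == 0) return(character())
  digits <- paste(groups, collapse = "")
  if (length(groups) == 1) return(digits)
  unique(c(normalize_punct(id_string), digits, paste(groups, collapse = " ")))
}

#' Expand a postcode into spaced and unspaced forms
#'
#' @param postcode Postcode text; case is normalized to upper.
#' @return For a well-formed postcode (2-4 alphanumeric outward code + 3
#'   alphanumeric inward code), the spaced and unspaced forms; otherwise the
#'   input as a single literal.
#' @export
#' @examples
#' expand_postcode_variants("SW9 6TJ")  # "SW9 6TJ" "SW96TJ"
expand_postcode_variants <- function(postcode) {
  if (length(postcode) == 0 || is.na(postcode)) return(character())
  pc <- split_postcode(postcode)
  if (is.null(pc)) return(stri_trans_toupper(stri_trim_both(postcode)))
  unique(c(paste(pc$outward, pc$inward), paste0(pc$outward, pc$inward)))
}

# NULL when malformed, else list(outward, inward), upper-case.
split_postcode <- function(postcode) {
  pc <- stri_trans_toupper(stri_trim_both(postcode))
  compact_pc <- stri_replace_all_regex(pc, "\\s+", "")
  n <- stri_length(compact_pc)
  if (!stri_detect_regex(compact_pc, "^[A-Z][A-Z0-9]{1,3}[A-Z0-9]{3}$") ||
      n < 5 || n > 7) {
    return(NULL)
  }
  list(outward = stri_sub(compact_pc, 1, n - 3), inward = stri_sub(compact_pc, n - 2, n))
}

#' Expand a telephone number into written groupings
#'
#' A 10-11 digit number is emitted as one unbroken digit string plus the
#' three standard UK groupings (5-3-3, 3-4-4 and 4-3-4 digit splits), each
#' also with brackets around the leading group.
#'
#' @param number Digit string (delimiters are ignored).
#' @return Character vector of variants; a number outside 10-11 digits is
#'   returned as a single literal.
#' @export
#' @examples
#' expand_phone_variants("00000000000")
expand_phone_variants <- function(number) {
  if (length(number) == 0 || is.na(number)) return(character())
  digits <- stri_replace_all_regex(number, "\\D", "")
  if (!stri_length(digits) %in% 10:11) return(digits)
  group <- function(a, b) {
    n <- stri_length(digits)
    g <- c(stri_sub(digits, 1, a), stri_sub(digits, a + 1, b), stri_sub(digits, b + 1, n))
    c(paste(g, collapse = " "),
      paste0("(", g[1], ") ", g[2], " ", g[3]))
  }
  unique(c(digits, group(5, 8), group(3, 7), group(4, 7)))
}

# Small closed set of glue words never useful as address evidence.
.address_stop_tokens <- c("the", "of", "at", "and")

#' Expand address lines into address-term entries
#'
#' Address lines are tokenized; stop tokens and single characters are
#' dropped; every token belonging to an alias group (road/rd, street/st, ...)
#' is expanded to all forms in its group. Pure-number tokens (house numbers)
#' are kept but flagged: the scanner only masks them adjacent to a worded
#' address term of the same patient.
#'
#' @param address A one-row tibble from [address()].
#' @param aliases Alias table, see [address_aliases()].
#' @return Tibble with columns `term` (lowercase) and `is_number`.
#' @export
#' @examples
#' expand_address_terms(address("12 Acacia Road"))
expand_address_terms <- function(address, aliases = address_aliases()) {
  lines <- unlist(address[, c("line1", "line2", "line3")], use.names = FALSE)
  lines <- lines[!is.na(lines)]
  if (length(lines) == 0) {
    return(tibble(term = character(), is_number = logical()))
  }
  tokens <- unlist(stri_split_regex(stri_trans_tolower(lines), "[^\\p{L}\\p{N}]+"))
  # one-letter fragments are dropped, but house numbers of any length stay
  tokens <- tokens[(stri_length(tokens) >= 2 | stri_detect_regex(tokens, "^\\p{N}+$")) &
                     !tokens %in% .address_stop_tokens & tokens != ""]
  expanded <- unique(unlist(lapply(tokens, function(tok) {
    hit <- keep(aliases, function(g) tok %in% g)
    if (length(hit)) unique(unlist(hit)) else tok
  })))
  tibble(term = expanded, is_number = stri_detect_regex(expanded, "^\\p{N}+$"))
}

new_entries <- function(surface, kind, subject = "patient") {
  surface <- normalize_punct(stri_trans_tolower(surface))
  surface <- surface[!is.na(surface) & surface != ""]
  if (length(surface) == 0) {
    return(tibble(surface = character(), kind = character(), subject = character()))
  }
  tibble(surface = surface, kind = kind, subject = subject)
}

#' Build the per-patient cleaning dictionary
#'
#' Collects every structured identifier of one patient, expands it into its
#' recognised surface variants, and stores both the literal entry set (for
#' dumps and literal matching) and the canonical values backing the
#' pattern-based scanners (date of birth, phone/ID digit strings, postcodes,
#' address terms). Key-contact names enter with `subject = "relative"` and
#' are masked with QQQQQ downstream; absent fields contribute nothing. The
#' dictionary is specific to one patient and differs between patients.
#'
#' @param record A one-row corpus tibble (see [source_record()]).
#' @param aliases Address alias table.
#' @return An object of class `cleaning_dictionary`.
#' @export
#' @examples
#' rec <- source_record("p1", "Joe", "Bloggs", date_of_birth = "1987-08-20",
#'                      trust_id = "12-34-56",
#'                      addresses = address(postcode = "SW9 6TJ"))
#' build_dictionary(rec)
build_dictionary <- function(record, aliases = address_aliases()) {
  stopifnot(nrow(record) == 1)

  name_tokens <- unlist(lapply(
    c(record$first_name, record$middle_name, record$last_name, record$nickname),
    strip_name_delimiters
  ))
  kc <- record$key_contacts[[1]]
  contact_tokens <- unlist(lapply(
    c(kc$first_name, kc$last_name), strip_name_delimiters
  ))

  dob <- record$date_of_birth
  date_variants <- expand_date_variants(dob)
  word_shaped <- stri_detect_regex(date_variants, "\\p{L}")

  phones <- record$phone_numbers[[1]]
  phone_digits <- unique(stri_replace_all_regex(phones, "\\D", ""))
  phone_digits <- phone_digits[stri_length(phone_digits) > 0]

  nhs_digits <- stri_replace_all_regex(record$nhs_number %||% NA_character_, "\\D", "")
  trust_digits <- stri_replace_all_regex(record$trust_id %||% NA_character_, "\\D", "")

  addr <- record$addresses[[1]]
  postcodes <- addr$postcode[!is.na(addr$postcode)]
  canonical_postcodes <- unique(unlist(lapply(postcodes, function(pc) {
    sp <- split_postcode(pc)
    if (is.null(sp)) stri_trans_toupper(stri_trim_both(pc)) else paste(sp$outward, sp$inward)
  })))
  address_terms <- if (nrow(addr)) {
    distinct(map_dfr(seq_len(nrow(addr)),
                     function(i) expand_address_terms(addr[i, ], aliases)))
  } else {
    tibble(term = character(), is_number = logical())
  }

  entries <- bind_rows(
    new_entries(name_tokens, "name"),
    new_entries(contact_tokens, "name", subject = "relative"),
    new_entries(date_variants[!word_shaped], "number_date"),
    new_entries(date_variants[word_shaped], "word_date"),
    new_entries(unlist(lapply(phones, expand_phone_variants)), "phone"),
    new_entries(expand_id_variants(record$nhs_number), "nhs_number"),
    new_entries(expand_id_variants(record$trust_id), "trust_id"),
    new_entries(unlist(lapply(postcodes, expand_postcode_variants)), "postcode"),
    new_entries(address_terms$term, "address_term")
  ) |> distinct()

  canonical_ids <- c(
    if (!is.na(nhs_digits) && stri_length(nhs_digits)) stats::setNames(nhs_digits, "nhs_number"),
    if (!is.na(trust_digits) && stri_length(trust_digits)) stats::setNames(trust_digits, "trust_id")
  )

  structure(
    list(
      patient_id = record$patient_id,
      entries = entries,
      canonical_dob = if (is.na(dob)) NULL else dob,
      canonical_phones = phone_digits,
      canonical_ids = canonical_ids,
      canonical_postcodes = canonical_postcodes,
      address_terms = address_terms
    ),
    class = "cleaning_dictionary"
  )
}

#' @export
print.cleaning_dictionary <- function(x, ...) {
  cat("<cleaning_dictionary> patient", x$patient_id, "\n")
  cat("  literal entries:", nrow(x$entries), "\n")
  counts <- count(x$entries, .data$kind)
  for (i in seq_len(nrow(counts))) {
    cat("   ", counts$kind[i], ":", counts$n[i], "\n")
  }
  invisible(x)
}

#' @describeIn build_dictionary Literal entry set as a tibble
#'   (`surface`, `kind`, `subject`).
#' @param x A `cleaning_dictionary`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cleaning_dictionary <- function(x, ...) x$entries

#' Dump or load a cleaning dictionary as JSON
#'
#' One file per patient; intended for debugging and cross-checks.
#'
#' @param dict A `cleaning_dictionary`.
#' @param file Path of the JSON file.
#' @return `dump_dictionary()` returns `file` invisibly; `load_dictionary()`
#'   returns a `cleaning_dictionary`.
#' @export
dump_dictionary <- function(dict, file) {
  x <- dict
  x$canonical_dob <- if (is.null(x$canonical_dob)) NULL else format(x$canonical_dob, "%Y-%m-%d")
  x$canonical_ids <- as.list(x$canonical_ids)
  jsonlite::write_json(unclass(x), file, auto_unbox = TRUE, null = "null",
                       dataframe = "columns")
  invisible(file)
}

#' @rdname dump_dictionary
#' @export
load_dictionary <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  x$entries <- as_tibble(as.data.frame(x$entries, stringsAsFactors = FALSE))
  if (nrow(x$entries) == 0) x$entries <- new_entries(character(), character())
  x$address_terms <- as_tibble(as.data.frame(x$address_terms, stringsAsFactors = FALSE))
  if (nrow(x$address_terms) == 0) {
    x$address_terms <- tibble(term = character(), is_number = logical())
  }
  x$canonical_dob <- if (is.null(x$canonical_dob)) NULL else as.Date(x$canonical_dob)
  x$canonical_phones <- as.character(x$canonical_phones %||% character())
  x$canonical_ids <- unlist(x$canonical_ids) %||% character()
  x$canonical_postcodes <- as.character(x$canonical_postcodes %||% character())
  structure(x, class = "cleaning_dictionary")
}
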