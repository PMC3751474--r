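# Shared constants: punctuation dialects, month tables, alias table, scan config.

# Apostrophe-like characters treated as one dialect (straight, curly, modifier).
.apostrophes <- c("'", "’", "‘", "ʼ")

# Hyphen-like characters treated as one delimiter dialect.
.dashes <- c("-", "–", "—")

.apostrophe_class <- paste0("[", paste(.apostrophes, collapse = ""), "]")
.dash_class <- paste0("[", paste(.dashes, collapse = ""), "]")

# Normalize curly apostrophes and en/em dashes to their ASCII forms. Used when
# storing dictionary literals so that matching is dialect-independent.
normalize_punct <- function(x) {
  x <- stri_replace_all_regex(x, .apostrophe_class, "'")
  stri_replace_all_regex(x, .dash_class, "-")
}

.month_table <- tibble::tibble(
  number = 1:12,
  full = c(
    "January", "February", "March", "April", "May", "June",
    "July", "August", "September", "October", "November", "December"
  ),
  abbrev = c(
    "Jan", "Feb", "Mar", "Apr", "May", "Jun",
    "Jul", "Aug", "Sep", "Oct", "Nov", "Dec"
  )
)

# "1" -> "1st", "22" -> "22nd", "13" -> "13th"
ordinal_suffix <- function(day) {
  vapply(as.integer(day), function(d) {
    if (d %% 100 %in% 11:13) return("th")
    switch(as.character(d %% 10), "1" = "st", "2" = "nd", "3" = "rd", "th")
  }, character(1))
}

#' Address alias table
#'
#' Groups of interchangeable address words (road/rd, street/st, ...). The
#' default table ships as an editable YAML file under
#' `inst/extdata/address_aliases.yaml`; each list element is one equivalence
#' group.
#'
#' @param path Path to a YAML file holding a list of character vectors. The
#'   default reads the table bundled with the package.
#' @return A list of lowercase character vectors, one per alias group.
#' @export
#' @examples
#' address_aliases()[[1]]
address_aliases <- function(path = system.file("extdata", "address_aliases.yaml",
                                               package = "deidr")) {
  groups <- yaml::read_yaml(path)
  lapply(groups, function(g) stri_trans_tolower(as.character(g)))
}

#' Scanner configuration
#'
#' Bundles the tunable pieces of the free-text scanner: masking strings, the
#' sentence-end punctuation set, the address alias table, and which scanners
#' run.
#'
#' @param mask_patient Replacement for patient identifiers (default `"ZZZZZ"`).
#' @param mask_relative Replacement for relative / close-contact identifiers
#'   (default `"QQQQQ"`).
#' @param sentence_punct Characters accepted as sentence-end suffixes after a
#'   token (full stop, comma, colon, semicolon, hyphen).
#' @param aliases Address alias table, see [address_aliases()].
#' @param scanners Character vector naming the scanners to run.
#' @return A list of class `scrub_config`.
#' @export
scrub_config <- function(mask_patient = "ZZZZZ",
                         mask_relative = "QQQQQ",
                         sentence_punct = c(".", ",", ":", ";", "-"),
                         aliases = address_aliases(),
                         scanners = c("names", "number_dates", "word_dates",
                                      "postcodes", "phones_ids", "addresses")) {
  structure(
    list(
      mask_patient = mask_patient,
      mask_relative = mask_relative,
      sentence_punct = sentence_punct,
      aliases = aliases,
      scanners = scanners
    ),
    class = "scrub_config"
  )
}
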