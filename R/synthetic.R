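# Synthetic patient corpus with gold-standard identifier spans. All names,
# addresses and numbers are fictitious, drawn from bundled wordlists (no
# population registries). The generator emulates the record shape the
# de-identifier assumes: near-complete structured-field coverage, identifier
# mentions written across the full variant grammar, plus two designed
# failure classes - misspelt mentions and identifiers mentioned in text but
# never entered in structured fields.

# Fictitious wordlists. The first-name list deliberately includes ambiguous
# common-word names (mark, summer, ruby) to exercise over-masking.
.first_names <- c(
  "Mark", "Summer", "Ruby", "Joe", "Anna", "Tessa", "Rohan", "Callum", "Priya",
  "Delia", "Marcus", "Yusuf", "Ingrid", "Leona", "Barnaby", "Cerys", "Dmitri",
  "Farrah", "Gideon", "Hattie", "Imogen", "Jasper", "Keziah", "Lorcan"
)
.last_names <- c(
  "Bloggs", "Dunn", "Okafor", "Petrov", "Whitlow", "Garrity", "Sandhu",
  "Macrae", "O'Connell", "Vann", "Ferreira", "Kowalski", "Ashworth", "Boland",
  "Cavendish", "D'Souza", "Eastwood", "Falk", "Grantham", "Hartley-Price"
)
.nicknames <- c(
  "Mobo", "Bea", "Kip", "Dot", "Taz", "Winnie", "Sol", "Effie", "Gus", "Nell",
  "Pip", "Ozzy"
)
.street_names <- c(
  "Acacia", "Bramley", "Cedarwood", "Delverton", "Elmfield", "Foxglove",
  "Garrick", "Hazelmere", "Ivydale", "Juniper", "Kestrel", "Larkspur"
)
.street_types <- c("Road", "Street", "Avenue", "Close", "Lane", "Court", "Drive")
.postcode_areas <- c("SW9", "EN1", "SE5", "BR3", "CR0", "N16", "E8", "KT2")

# Neutral clinical filler. Deliberately free of digits, month words, street
# words and every wordlist name, so filler never collides with a dictionary.
.note_fillers <- c(
  "Seen in clinic for routine review.",
  "Reports improved sleep and appetite.",
  "Medication unchanged; no side effects reported.",
  "Attended with support worker; engagement good.",
  "Plan: continue current care package.",
  "Mood described as settled over recent weeks.",
  "Discussed coping strategies during the session.",
  "Will be reviewed again by the community team.",
  "No concerns raised regarding risk.",
  "Follow-up arranged with the duty clinician."
)

#' Corruption profile for the synthetic generator
#'
#' Defines the study conditions the corpus emulates. Structured-field
#' coverage defaults mirror a large source system in which first and last
#' name are mandatory, 99.7% of patients have a valid date of birth and
#' 98.5% have at least one address. The corruption mix defaults produce a
#' residual-identifier pool of roughly three misspellings to one un-entered
#' identifier.
#'
#' @param p_misspell Probability that a textual identifier mention is
#'   perturbed at edit distance one (and therefore designed to be missed).
#' @param p_unentered Probability that a mention uses an identifier absent
#'   from the structured fields (nickname or old address).
#' @param dob_coverage Fraction of patients with a date of birth.
#' @param address_coverage Fraction of patients with at least one address.
#' @param notes_per_patient Notes generated per patient.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `corruption_profile`.
#' @export
corruption_profile <- function(p_misspell = 0.15, p_unentered = 0.05,
                               dob_coverage = 0.997, address_coverage = 0.985,
                               notes_per_patient = 5, seed = 1L) {
  probs <- c(p_misspell, p_unentered, dob_coverage, address_coverage)
  if (any(probs < 0 | probs > 1)) {
    abort("configuration error: probabilities must lie in [0, 1]")
  }
  if (p_misspell + p_unentered > 1) {
    abort("configuration error: p_misspell + p_unentered must not exceed 1")
  }
  if (notes_per_patient < 1) {
    abort("configuration error: notes_per_patient must be >= 1")
  }
  structure(
    list(p_misspell = p_misspell, p_unentered = p_unentered,
         dob_coverage = dob_coverage, address_coverage = address_coverage,
         notes_per_patient = as.integer(notes_per_patient),
         seed = as.integer(seed)),
    class = "corruption_profile"
  )
}

random_digits <- function(n) paste(sample(0:9, n, replace = TRUE), collapse = "")

random_postcode <- function() {
  paste0(sample(.postcode_areas, 1), " ", sample(1:9, 1),
         paste(sample(LETTERS[c(1:8, 10:14, 16:25)], 2, replace = TRUE), collapse = ""))
}

random_dob <- function() {
  as.Date(sample.int(as.integer(as.Date("2005-12-31")) -
                       as.integer(as.Date("1930-01-01")), 1) - 1,
          origin = "1930-01-01")
}

# single-character substitution, insertion or transposition that never
# recreates the original string
perturb_string <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  repeat {
    op <- sample(c("sub", "ins", "swap"), 1)
    if (op == "swap" && n < 2) next
    out <- switch(op,
      sub = {
        at <- which(stri_detect_regex(chars, "[\\p{L}\\p{N}]"))
        i <- at[sample.int(length(at), 1)]
        pool <- if (stri_detect_regex(chars[i], "\\p{N}")) as.character(0:9) else letters
        repl <- pool[!pool %in% stri_trans_tolower(chars[i])][sample.int(length(pool) - 1, 1)]
        if (stri_detect_regex(chars[i], "\\p{Lu}")) repl <- stri_trans_toupper(repl)
        paste0(stri_sub(s, 1, i - 1), repl, stri_sub(s, i + 1, n))
      },
      ins = {
        i <- sample.int(n, 1)
        paste0(stri_sub(s, 1, i), letters[sample.int(26, 1)], stri_sub(s, i + 1, n))
      },
      swap = {
        i <- sample.int(n - 1, 1)
        if (chars[i] == chars[i + 1]) next
        chars2 <- chars
        chars2[c(i, i + 1)] <- chars2[c(i + 1, i)]
        paste(chars2, collapse = "")
      }
    )
    if (!identical(out, s)) return(out)
  }
}

# safety-net corruption: wound every alphanumeric token so that no scanner
# can possibly recognise the result (used only if repeated single-edit
# perturbation keeps landing on catchable strings)
corrupt_every_token <- function(s) {
  stri_replace_all_regex(s, "([\\p{L}\\p{N}])([\\p{L}\\p{N}]+)", "$1x$2")
}

generate_patient <- function(idx, profile) {
  fn <- sample(.first_names, 1)
  ln <- sample(.last_names, 1)
  has_addr <- runif(1) < profile$address_coverage
  addr <- if (has_addr) {
    address(
      line1 = paste(sample(1:99, 1), sample(.street_names, 1), sample(.street_types, 1)),
      postcode = random_postcode()
    )
  } else {
    empty_addresses()
  }
  kc <- if (runif(1) < 0.5) {
    tibble(first_name = sample(setdiff(.first_names, fn), 1),
           last_name = sample(setdiff(.last_names, ln), 1))
  } else {
    empty_contacts()
  }
  source_record(
    patient_id = sprintf("P%04d", idx),
    first_name = fn,
    middle_name = if (runif(1) < 0.3) sample(setdiff(.first_names, fn), 1) else NA,
    last_name = ln,
    nickname = if (runif(1) < 0.25) sample(.nicknames, 1) else NA,
    date_of_birth = if (runif(1) < profile$dob_coverage) random_dob() else NA,
    nhs_number = if (runif(1) < 0.9) random_digits(10) else NA,
    trust_id = if (runif(1) < 0.95) {
      paste(c(random_digits(2), random_digits(2), random_digits(2)), collapse = "-")
    } else {
      NA
    },
    phone_numbers = if (runif(1) < 0.8) paste0("07", random_digits(9)) else character(),
    addresses = addr,
    key_contacts = kc
  )
}

# ---- mention construction --------------------------------------------------

.name_formats <- c("plain", "possessive", "o_prefix", "line_start", "after_bracket")

# surface form of one mention; names are mentioned token-wise (the catch unit
# of the dictionary), with the format supplying possessives / O' prefixes
mention_surface <- function(kind, value, format_id, aliases) {
  switch(kind,
    name = switch(format_id,
      possessive = paste0(value, "'s"),
      o_prefix = paste0("O'", value),
      value
    ),
    date = ,
    number_date = ,
    word_date = expand_date_variants(value)[as.integer(stri_sub(format_id, 6))],
    phone = expand_phone_variants(value)[as.integer(stri_sub(format_id, 4))],
    nhs_number = ,
    trust_id = {
      v <- expand_id_variants(value)
      v[pmin(as.integer(stri_sub(format_id, 4)), length(v))]
    },
    postcode = {
      v <- expand_postcode_variants(value)
      if (format_id == "unspaced") v[length(v)] else v[1]
    },
    address_term = if (format_id == "alias") alias_swap(value, aliases) else value,
    value
  )
}

#' Inject one identifier mention into a note template
#'
#' @param note_template Template text containing the placeholder `{PI}`.
#' @param pi_value The identifier surface to insert.
#' @param format_id Free-form label recorded alongside the span.
#' @return A list with `text` and a one-row `span` tibble giving the exact
#'   0-based half-open offsets of the inserted surface.
#' @export
#' @examples
#' inject_mention("Discussed with {PI} today.", "Mark's", "possessive")
inject_mention <- function(note_template, pi_value, format_id = "plain") {
  at <- stri_locate_all_fixed(note_template, "{PI}")[[1]]
  if (is.na(at[1, 1])) abort("note_template must contain '{PI}'")
  s <- at[1, 1]
  text <- stri_replace_all_fixed(note_template, "{PI}", pi_value)
  list(
    text = text,
    span = tibble(start = s - 1L, end = s - 1L + stri_length(pi_value),
                  format_id = format_id)
  )
}

# pool of mentionable identifiers for one patient
mention_pool <- function(rec) {
  pool <- list()
  add <- function(kind, value, formats, subject = "patient") {
    pool[[length(pool) + 1]] <<- list(kind = kind, value = value,
                                      formats = formats, subject = subject)
  }
  for (nm in c(rec$first_name, rec$middle_name, rec$last_name, rec$nickname)) {
    for (tok in strip_name_delimiters(nm)) add("name", tok, .name_formats)
  }
  if (!is.na(rec$date_of_birth)) {
    nv <- length(expand_date_variants(rec$date_of_birth))
    add("date", rec$date_of_birth, paste0("date_", seq_len(nv)))
  }
  if (!is.na(rec$nhs_number)) add("nhs_number", rec$nhs_number, c("var1", "var2"))
  if (!is.na(rec$trust_id)) {
    add("trust_id", rec$trust_id,
        paste0("var", seq_along(expand_id_variants(rec$trust_id))))
  }
  for (ph in rec$phone_numbers[[1]]) {
    add("phone", ph, paste0("grp", seq_along(expand_phone_variants(ph))))
  }
  addr <- rec$addresses[[1]]
  if (nrow(addr) && !is.na(addr$postcode[1])) {
    add("postcode", addr$postcode[1], c("spaced", "unspaced"))
  }
  if (nrow(addr) && !is.na(addr$line1[1])) {
    add("address_term", addr$line1[1], c("verbatim", "alias"))
  }
  kc <- rec$key_contacts[[1]]
  if (nrow(kc)) {
    for (tok in strip_name_delimiters(kc$last_name[1])) {
      add("name", tok, c("plain", "possessive"), subject = "relative")
    }
  }
  pool
}

alias_swap <- function(line, aliases) {
  toks <- strsplit(line, " ")[[1]]
  low <- stri_trans_tolower(toks)
  for (i in seq_along(toks)) {
    grp <- keep(aliases, function(g) low[i] %in% g)
    if (length(grp)) {
      others <- setdiff(grp[[1]], low[i])
      if (length(others)) {
        repl <- others[sample.int(length(others), 1)]
        toks[i] <- paste0(stri_trans_toupper(stri_sub(repl, 1, 1)), stri_sub(repl, 2))
      }
    }
  }
  paste(toks, collapse = " ")
}

# would this surface, standing alone, be caught by the patient's scanners?
is_catchable <- function(surface, dict, config) {
  nrow(scrub_text(paste0("x ", surface, " x"), dict, config)$spans) > 0
}

unentered_surface <- function(rec, dict) {
  if (runif(1) < 0.5) {
    # a nickname used in conversation but never entered in the alias field
    cands <- .nicknames[!stri_trans_tolower(.nicknames) %in% dict$entries$surface]
    if (length(cands) == 0) cands <- "Binky"
    list(kind = "name", surface = cands[sample.int(length(cands), 1)])
  } else {
    # an old address that predates the structured record
    own <- stri_trans_tolower(unlist(strsplit(rec$addresses[[1]]$line1, " ")))
    streets <- .street_names[!stri_trans_tolower(.street_names) %in% own]
    list(kind = "address_term",
         surface = paste(sample(1:99, 1), streets[sample.int(length(streets), 1)],
                         sample(.street_types, 1)))
  }
}

build_note <- function(rec, dict, profile, config, aliases) {
  pool <- mention_pool(rec)
  n_mentions <- sample(1:3, 1)
  picks <- sample.int(length(pool), n_mentions, replace = length(pool) < n_mentions)

  pieces <- character()
  spans <- list()
  offset <- 0L
  add_piece <- function(txt) {
    pieces[[length(pieces) + 1]] <<- txt
    offset <<- offset + stri_length(txt)
  }
  add_piece(.note_fillers[sample.int(length(.note_fillers), 1)])

  for (p in picks) {
    item <- pool[[p]]
    u <- runif(1)
    status <- if (u < profile$p_unentered) "unentered"
      else if (u < profile$p_unentered + profile$p_misspell) "misspelt"
      else "clean"

    if (status == "unentered") {
      un <- unentered_surface(rec, dict)
      kind <- un$kind; subject <- "patient"; fmt <- "unentered"
      surface <- un$surface
    } else {
      kind <- item$kind; subject <- item$subject
      fmt <- item$formats[sample.int(length(item$formats), 1)]
      surface <- mention_surface(kind, item$value, fmt, aliases)
      if (kind == "date") {
        kind <- if (stri_detect_regex(surface, "\\p{L}")) "word_date" else "number_date"
      }
      if (status == "misspelt") {
        cand <- perturb_string(surface)
        tries <- 0
        while (is_catchable(cand, dict, config) && tries < 50) {
          cand <- perturb_string(surface)
          tries <- tries + 1
        }
        if (is_catchable(cand, dict, config)) cand <- corrupt_every_token(surface)
        surface <- cand
      }
    }

    lead_in <- switch(fmt,
      possessive = "Discussed ",
      o_prefix = "Seen with ",
      after_bracket = "(1)",
      line_start = "\n",
      "Noted "
    )
    trail <- c(" during review. ", ", as recorded. ", ". ")[sample.int(3, 1)]
    add_piece(if (fmt == "line_start") lead_in else paste0(" ", lead_in))
    span_start <- offset
    add_piece(surface)
    spans[[length(spans) + 1]] <- tibble(
      start = span_start, end = offset, kind = kind, subject = subject,
      status = status, surface = surface
    )
    add_piece(trail)
    add_piece(.note_fillers[sample.int(length(.note_fillers), 1)])
  }

  list(text = paste(pieces, collapse = ""), spans = bind_rows(spans))
}

#' Generate a synthetic corpus with gold-standard spans
#'
#' Every patient receives fictitious structured fields at the profile's
#' coverage rates and `notes_per_patient` notes whose identifier mentions
#' are drawn across the full variant grammar (all date shapes, phone
#' groupings, possessive, O'-prefixed, line-initial and bracketed name
#' contexts). Each mention is recorded as a gold span with a status: `clean`
#' spans are exactly what the scrubber is designed to catch; `misspelt` and
#' `unentered` spans are its designed misses and stay unmasked by
#' construction.
#'
#' @param n_patients Number of patients (>= 1).
#' @param profile A [corruption_profile()].
#' @param config A [scrub_config()] (the generator consults the alias table
#'   and dictionary literals when constructing designed misses).
#' @return A list with `records` (corpus tibble) and `gold` (span tibble:
#'   `patient_id`, `doc_id`, `start`, `end`, `kind`, `subject`, `status`,
#'   `surface`).
#' @export
#' @examples
#' gc <- generate_corpus(2, corruption_profile(0, 0, seed = 7))
#' gc$gold
generate_corpus <- function(n_patients, profile = corruption_profile(),
                            config = scrub_config()) {
  if (!inherits(profile, "corruption_profile")) {
    abort("configuration error: profile must be a corruption_profile()")
  }
  if (n_patients < 1) abort("configuration error: n_patients must be >= 1")
  local_seed(profile$seed)
  aliases <- config$aliases

  recs <- list()
  golds <- list()
  for (i in seq_len(n_patients)) {
    rec <- generate_patient(i, profile)
    dict <- build_dictionary(rec, aliases = aliases)
    docs <- list()
    for (k in seq_len(profile$notes_per_patient)) {
      note <- build_note(rec, dict, profile, config, aliases)
      doc_id <- sprintf("%s-D%02d", rec$patient_id, k)
      docs[[k]] <- document(doc_id, "event_note", note$text)
      if (nrow(note$spans)) {
        golds[[length(golds) + 1]] <- mutate(note$spans,
                                             patient_id = rec$patient_id,
                                             doc_id = doc_id, .before = 1)
      }
    }
    rec$documents <- list(bind_rows(docs))
    recs[[i]] <- rec
  }
  gold <- if (length(golds)) bind_rows(golds) else {
    tibble(patient_id = character(), doc_id = character(), start = integer(),
           end = integer(), kind = character(), subject = character(),
           status = character(), surface = character())
  }
  list(records = assert_corpus(bind_rows(recs)), gold = gold)
}
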