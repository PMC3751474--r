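# Whole-record de-identification: structured-field policy (strip / truncate /
# weaken / passthrough) plus scrubbing of every document in a configured scope.

#' Truncate a postcode to its outward code
#'
#' Only the first half (3 or 4 characters) of the postcode is retained,
#' masking identity while keeping coarse geography.
#'
#' @param postcode Postcode text.
#' @return The outward code, or `NA` for malformed input.
#' @export
#' @examples
#' truncate_postcode("SW9 6TJ")   # "SW9"
#' truncate_postcode("SW16 6TJ")  # "SW16"
truncate_postcode <- function(postcode) {
  vapply(postcode, function(pc) {
    if (is.na(pc)) return(NA_character_)
    sp <- split_postcode(pc)
    if (is.null(sp)) NA_character_ else sp$outward
  }, character(1), USE.NAMES = FALSE)
}

#' Weaken a date of birth to month and year
#'
#' @param dob A `Date` (or `NA`).
#' @return A list with integer `month` and `year`, or `NULL` when absent.
#' @export
#' @examples
#' weaken_dob(as.Date("1987-08-20"))  # month 8, year 1987
weaken_dob <- function(dob) {
  if (length(dob) == 0 || is.na(dob)) return(NULL)
  list(month = as.integer(format(dob, "%m")), year = as.integer(format(dob, "%Y")))
}

.pi_fields <- c("first_name", "middle_name", "last_name", "nickname",
                "nhs_number", "trust_id", "phone_numbers", "key_contacts",
                "address_lines", "postcode", "date_of_birth")

#' Field policy for structured identifiers
#'
#' Maps every structured identifier field to one action:
#' `dictionary_and_strip` (feed the dictionary, then remove the field
#' entirely), `dictionary_and_truncate_postcode` (feed the dictionary, keep
#' the outward code), `weaken_dob` (keep month and year only), or
#' `passthrough`. The scope list names the free-text fields the scrubber
#' runs over; documents outside it pass through verbatim.
#'
#' @param actions Named character vector `field = action` overriding the
#'   defaults.
#' @param scopes Character vector of scope names to scrub.
#' @return An object of class `field_policy`: a tibble (`field`, `action`)
#'   with a `scopes` attribute.
#' @export
#' @examples
#' default_field_policy()
field_policy <- function(actions = character(),
                         scopes = c("summary", "event_note",
                                    "correspondence", "ward_progress")) {
  if (length(scopes) == 0) abort("configuration error: scope list must be non-empty")
  acts <- c(
    first_name = "dictionary_and_strip", middle_name = "dictionary_and_strip",
    last_name = "dictionary_and_strip", nickname = "dictionary_and_strip",
    nhs_number = "dictionary_and_strip", trust_id = "dictionary_and_strip",
    phone_numbers = "dictionary_and_strip", key_contacts = "dictionary_and_strip",
    address_lines = "dictionary_and_strip",
    postcode = "dictionary_and_truncate_postcode",
    date_of_birth = "weaken_dob"
  )
  bad <- setdiff(names(actions), .pi_fields)
  if (length(bad)) {
    abort(paste0("configuration error: unknown policy field '", bad[1], "'"))
  }
  allowed <- c("dictionary_and_strip", "dictionary_and_truncate_postcode",
               "weaken_dob", "passthrough")
  if (length(actions) && !all(actions %in% allowed)) {
    abort("configuration error: unknown policy action")
  }
  acts[names(actions)] <- actions
  missing <- setdiff(.pi_fields, names(acts))
  if (length(missing)) {
    abort(paste0("configuration error: no action for field '", missing[1], "'"))
  }
  structure(
    tibble(field = names(acts), action = unname(acts)),
    scopes = scopes,
    class = c("field_policy", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname field_policy
#' @export
default_field_policy <- function() field_policy()

#' Read a field policy from YAML
#'
#' The YAML file may define `actions:` (a field-to-action map) and `scopes:`
#' (a list of scope names).
#'
#' @param path Path to the YAML file.
#' @return A `field_policy`.
#' @export
read_policy_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  field_policy(
    actions = unlist(cfg$actions) %||% character(),
    scopes = as.character(cfg$scopes %||% formals(field_policy)$scopes)
  )
}

policy_action <- function(policy, field) policy$action[match(field, policy$field)]

#' De-identify a corpus of patient records
#'
#' For each patient: builds the cleaning dictionary, applies the
#' structured-field policy (strip, truncate postcode to outward code, weaken
#' date of birth to month + year), scrubs every document whose scope is in
#' the policy's scope list, and assigns a pseudonymous identifier (a keyed
#' hash of the patient id; the key is run-scoped and discarded, so no
#' linkage is retained). Matched surface forms are never logged - the audit
#' carries span offsets and kinds only.
#'
#' @param records A corpus tibble.
#' @param policy A [field_policy()].
#' @param config A [scrub_config()].
#' @param secret Optional key for the pseudonymous-id hash; supply one to
#'   make repeated runs byte-identical. The default draws a fresh key per
#'   run.
#' @return An object of class `deid_corpus`: a list with `records` (the
#'   de-identified tibble) and `spans` (audit tibble of masked spans on
#'   original-text coordinates: `patient_id`, `doc_id`, `start`, `end`,
#'   `kind`, `subject`, `replacement`).
#' @export
#' @examples
#' rec <- source_record("p1", "Mark", "Dunn",
#'   documents = document("d1", "event_note", "Nurse informed Mark."))
#' deidentify(rec)$records$documents[[1]]$text
deidentify <- function(records, policy = default_field_policy(),
                       config = scrub_config(), secret = NULL) {
  assert_corpus(records)
  scopes <- attr(policy, "scopes")
  secret <- secret %||% paste(sample(c(letters, 0:9), 24, replace = TRUE), collapse = "")

  strip_chr <- function(field, value) {
    if (identical(policy_action(policy, field), "passthrough")) value else NA_character_
  }

  all_spans <- list()
  out_rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    dict <- build_dictionary(rec, aliases = config$aliases)

    docs <- rec$documents[[1]]
    doc_spans <- empty_spans() |> mutate(replacement = character(), doc_id = character())
    if (nrow(docs)) {
      scrubbed <- lapply(seq_len(nrow(docs)), function(j) {
        if (docs$scope_id[j] %in% scopes) {
          scrub_text(docs$text[j], dict, config)
        } else {
          list(text = docs$text[j], spans = NULL)
        }
      })
      docs$text <- vapply(scrubbed, function(s) s$text, character(1))
      doc_spans <- map_dfr(seq_along(scrubbed), function(j) {
        sp <- scrubbed[[j]]$spans
        if (is.null(sp) || nrow(sp) == 0) return(NULL)
        mutate(sp, doc_id = docs$doc_id[j], .before = 1)
      })
    }
    if (!is.null(doc_spans) && nrow(doc_spans)) {
      all_spans[[length(all_spans) + 1]] <<- mutate(doc_spans, patient_id = rec$patient_id,
                                                    .before = 1)
    }

    dob_weak <- if (identical(policy_action(policy, "date_of_birth"), "weaken_dob")) {
      weaken_dob(rec$date_of_birth)
    } else {
      NULL
    }
    addr <- rec$addresses[[1]]
    pc_action <- policy_action(policy, "postcode")
    outward <- if (identical(pc_action, "dictionary_and_truncate_postcode") && nrow(addr)) {
      oc <- truncate_postcode(addr$postcode)
      oc[!is.na(oc)]
    } else {
      character()
    }

    tibble(
      pseudonymous_id = paste0("R", stri_sub(hash(paste0(secret, ":", rec$patient_id)), 1, 12)),
      first_name = strip_chr("first_name", rec$first_name),
      middle_name = strip_chr("middle_name", rec$middle_name),
      last_name = strip_chr("last_name", rec$last_name),
      nickname = strip_chr("nickname", rec$nickname),
      nhs_number = strip_chr("nhs_number", rec$nhs_number),
      trust_id = strip_chr("trust_id", rec$trust_id),
      birth_month = dob_weak$month %||% NA_integer_,
      birth_year = dob_weak$year %||% NA_integer_,
      postcode_outward = list(outward),
      documents = list(docs)
    )
  })

  spans <- if (length(all_spans)) bind_rows(all_spans) else {
    tibble(patient_id = character(), doc_id = character(), start = integer(),
           end = integer(), kind = character(), subject = character(),
           replacement = character())
  }
  structure(
    list(records = bind_rows(out_rows), spans = spans),
    class = "deid_corpus"
  )
}

#' @export
print.deid_corpus <- function(x, ...) {
  cat("<deid_corpus>", nrow(x$records), "patients,",
      nrow(x$spans), "masked spans\n")
  invisible(x)
}

#' @describeIn deidentify Audit spans as a tibble.
#' @param x A `deid_corpus`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.deid_corpus <- function(x, ...) x$spans

#' @describeIn deidentify One row of masked-span counts by kind.
#' @exportS3Method generics::glance
glance.deid_corpus <- function(x, ...) {
  counts <- count(x$spans, .data$kind)
  out <- tibble(n_patients = nrow(x$records), n_spans = nrow(x$spans))
  if (nrow(counts)) {
    wide <- tidyr::pivot_wider(counts, names_from = "kind", values_from = "n",
                               names_prefix = "n_")
    out <- bind_cols(out, wide)
  }
  out
}

#' Write a de-identified corpus as XML
#'
#' Stripped fields are absent from the output entirely; only the
#' pseudonymous id, the weak identifiers (birth month/year, postcode outward
#' code) and the scrubbed documents are written.
#'
#' @param deid A `deid_corpus`.
#' @param file Path, or `NULL` to return the XML string.
#' @return `file` invisibly (or the XML string).
#' @export
write_deid_xml <- function(deid, file = NULL) {
  recs <- deid$records
  doc <- xml2::xml_new_root("corpus")
  for (i in seq_len(nrow(recs))) {
    rec <- recs[i, ]
    p <- xml2::xml_add_child(doc, "patient", id = rec$pseudonymous_id)
    ids <- xml2::xml_add_child(p, "identifiers")
    for (f in c("first_name", "middle_name", "last_name", "nickname",
                "nhs_number", "trust_id")) {
      add_text_child(ids, f, rec[[f]])
    }
    if (!is.na(rec$birth_month)) {
      xml2::xml_add_child(ids, "birth_month", as.character(rec$birth_month))
      xml2::xml_add_child(ids, "birth_year", as.character(rec$birth_year))
    }
    for (oc in rec$postcode_outward[[1]]) {
      xml2::xml_add_child(ids, "postcode_outward", oc)
    }
    docs <- rec$documents[[1]]
    dn <- xml2::xml_add_child(p, "documents")
    if (nrow(docs)) {
      for (j in seq_len(nrow(docs))) {
        d <- xml2::xml_add_child(dn, "document", docs$text[j],
                                 id = docs$doc_id[j], scope = docs$scope_id[j])
        if (!is.na(docs$date[j])) {
          xml2::xml_set_attr(d, "date", format(docs$date[j], "%Y-%m-%d"))
        }
      }
    }
  }
  write_doc(doc, file)
}

#' Export masked spans as a standoff annotation table
#'
#' @param spans A span tibble (e.g. `tidy()` of a `deid_corpus`).
#' @param file TSV path.
#' @return `file`, invisibly.
#' @export
write_spans_tsv <- function(spans, file) {
  cols <- intersect(c("patient_id", "doc_id", "start", "end", "kind",
                      "subject", "replacement", "status"), names(spans))
  utils::write.table(spans[, cols], file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_spans_tsv
#' @export
read_spans_tsv <- function(file) {
  as_tibble(utils::read.table(file, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}
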