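# Per-patient XML interchange format. One <patient> element per patient,
# mirroring the record hierarchy:
#
#   <patient id="...">
#     <identifiers>
#       <first_name>..</first_name> ... <date_of_birth>YYYY-MM-DD</date_of_birth>
#       <phone_numbers><phone>..</phone>...</phone_numbers>
#       <addresses><address status="current"><line1>..</line1>..<postcode>..</postcode></address></addresses>
#       <key_contacts><key_contact><first_name>..</first_name><last_name>..</last_name></key_contact></key_contacts>
#     </identifiers>
#     <documents><document id=".." scope=".." date="..">free text</document></documents>
#   </patient>
#
# Absent fields are absent elements, never empty-string sentinels. A corpus
# file wraps patients in a <corpus> root. The element names are documented in
# inst/extdata/record-schema.md. Encoding is UTF-8 throughout.

.scalar_fields <- c("first_name", "middle_name", "last_name", "nickname",
                    "date_of_birth", "nhs_number", "trust_id")

xml_child_text <- function(node, name) {
  child <- xml2::xml_find_first(node, name)
  if (inherits(child, "xml_missing")) NA_character_ else xml2::xml_text(child)
}

parse_patient_node <- function(node) {
  known <- c("identifiers", "documents")
  kids <- xml2::xml_name(xml2::xml_children(node))
  bad <- setdiff(kids, known)
  if (length(bad)) {
    abort(paste0("schema error: unknown element <", bad[1], "> under <patient>"))
  }
  ids <- xml2::xml_find_first(node, "identifiers")
  vals <- if (inherits(ids, "xml_missing")) {
    stats::setNames(rep(NA_character_, length(.scalar_fields)), .scalar_fields)
  } else {
    id_kids <- xml2::xml_name(xml2::xml_children(ids))
    bad <- setdiff(id_kids, c(.scalar_fields, "phone_numbers", "addresses", "key_contacts"))
    if (length(bad)) {
      abort(paste0("schema error: unknown element <", bad[1], "> under <identifiers>"))
    }
    stats::setNames(vapply(.scalar_fields, function(f) xml_child_text(ids, f),
                           character(1)), .scalar_fields)
  }

  phones <- xml2::xml_text(xml2::xml_find_all(node, "identifiers/phone_numbers/phone"))

  addr_nodes <- xml2::xml_find_all(node, "identifiers/addresses/address")
  addresses <- if (length(addr_nodes) == 0) empty_addresses() else {
    map_dfr(addr_nodes, function(a) {
      address(
        line1 = xml_child_text(a, "line1"), line2 = xml_child_text(a, "line2"),
        line3 = xml_child_text(a, "line3"), postcode = xml_child_text(a, "postcode"),
        status = xml2::xml_attr(a, "status") %|na|% "current"
      )
    })
  }

  kc_nodes <- xml2::xml_find_all(node, "identifiers/key_contacts/key_contact")
  key_contacts <- if (length(kc_nodes) == 0) empty_contacts() else {
    map_dfr(kc_nodes, function(k) {
      tibble(first_name = xml_child_text(k, "first_name") %||% NA_character_,
             last_name = xml_child_text(k, "last_name") %||% NA_character_)
    })
  }

  doc_nodes <- xml2::xml_find_all(node, "documents/document")
  documents <- if (length(doc_nodes) == 0) empty_documents() else {
    map_dfr(doc_nodes, function(d) {
      document(
        doc_id = xml2::xml_attr(d, "id"),
        scope_id = xml2::xml_attr(d, "scope"),
        text = xml2::xml_text(d),
        date = xml2::xml_attr(d, "date")
      )
    })
  }

  source_record(
    patient_id = xml2::xml_attr(node, "id"),
    first_name = vals[["first_name"]], middle_name = vals[["middle_name"]],
    last_name = vals[["last_name"]], nickname = vals[["nickname"]],
    date_of_birth = vals[["date_of_birth"]], nhs_number = vals[["nhs_number"]],
    trust_id = vals[["trust_id"]], phone_numbers = phones,
    addresses = addresses, key_contacts = key_contacts, documents = documents
  )
}

`%|na|%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x)) y else x

#' Read a per-patient XML record
#'
#' @param xml_source Path, connection, or raw/character XML for a single
#'   `<patient>` document.
#' @return A one-row corpus tibble (see [source_record()]).
#' @export
read_record <- function(xml_source) {
  doc <- xml2::read_xml(xml_source)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "patient") {
    abort(paste0("schema error: expected <patient> root, found <",
                 xml2::xml_name(root), ">"))
  }
  parse_patient_node(root)
}

#' Read an XML corpus of patient records
#'
#' @param xml_source Path, connection, or raw/character XML. The root may be a
#'   `<corpus>` wrapping `<patient>` elements, or a single `<patient>`.
#' @return A corpus tibble, one row per patient.
#' @export
read_corpus_xml <- function(xml_source) {
  doc <- xml2::read_xml(xml_source)
  root <- xml2::xml_root(doc)
  nodes <- switch(xml2::xml_name(root),
    corpus = xml2::xml_find_all(root, "patient"),
    patient = list(root),
    abort(paste0("schema error: expected <corpus> or <patient> root, found <",
                 xml2::xml_name(root), ">"))
  )
  out <- map_dfr(nodes, parse_patient_node)
  assert_corpus(out)
}

add_text_child <- function(parent, name, value) {
  if (length(value) == 1 && !is.na(value)) {
    xml2::xml_add_child(parent, name, as.character(value))
  }
  invisible(parent)
}

build_patient_node <- function(parent, rec) {
  p <- xml2::xml_add_child(parent, "patient", id = rec$patient_id)
  ids <- xml2::xml_add_child(p, "identifiers")
  add_text_child(ids, "first_name", rec$first_name)
  add_text_child(ids, "middle_name", rec$middle_name)
  add_text_child(ids, "last_name", rec$last_name)
  add_text_child(ids, "nickname", rec$nickname)
  if (!is.na(rec$date_of_birth)) {
    xml2::xml_add_child(ids, "date_of_birth", format(rec$date_of_birth, "%Y-%m-%d"))
  }
  add_text_child(ids, "nhs_number", rec$nhs_number)
  add_text_child(ids, "trust_id", rec$trust_id)
  phones <- rec$phone_numbers[[1]]
  if (length(phones)) {
    pn <- xml2::xml_add_child(ids, "phone_numbers")
    for (ph in phones) xml2::xml_add_child(pn, "phone", ph)
  }
  addr <- rec$addresses[[1]]
  if (nrow(addr)) {
    an <- xml2::xml_add_child(ids, "addresses")
    for (i in seq_len(nrow(addr))) {
      a <- xml2::xml_add_child(an, "address", status = addr$status[i])
      add_text_child(a, "line1", addr$line1[i])
      add_text_child(a, "line2", addr$line2[i])
      add_text_child(a, "line3", addr$line3[i])
      add_text_child(a, "postcode", addr$postcode[i])
    }
  }
  kc <- rec$key_contacts[[1]]
  if (nrow(kc)) {
    kn <- xml2::xml_add_child(ids, "key_contacts")
    for (i in seq_len(nrow(kc))) {
      k <- xml2::xml_add_child(kn, "key_contact")
      add_text_child(k, "first_name", kc$first_name[i])
      add_text_child(k, "last_name", kc$last_name[i])
    }
  }
  docs <- rec$documents[[1]]
  dn <- xml2::xml_add_child(p, "documents")
  if (nrow(docs)) {
    for (i in seq_len(nrow(docs))) {
      d <- xml2::xml_add_child(dn, "document", docs$text[i],
                               id = docs$doc_id[i], scope = docs$scope_id[i])
      if (!is.na(docs$date[i])) {
        xml2::xml_set_attr(d, "date", format(docs$date[i], "%Y-%m-%d"))
      }
    }
  }
  invisible(p)
}

# Serialization never pretty-prints: whitespace inside text nodes must stay
# byte-identical so span offsets survive a round-trip.
write_doc <- function(doc, file) {
  if (is.null(file)) {
    as.character(doc, options = "no_declaration")
  } else {
    xml2::write_xml(doc, file, options = "as_xml")
    invisible(file)
  }
}

#' Write patient records as XML
#'
#' Absent fields are omitted entirely (never written as empty elements), so a
#' stripped field leaves no trace in the output. Text nodes are written
#' verbatim, keeping character offsets stable.
#'
#' @param records A corpus tibble.
#' @param file Path to write to, or `NULL` to return the XML as a string.
#' @return `file`, invisibly (or the XML string when `file` is `NULL`).
#' @export
write_corpus_xml <- function(records, file = NULL) {
  assert_corpus(records)
  doc <- xml2::xml_new_root("corpus")
  for (i in seq_len(nrow(records))) build_patient_node(doc, records[i, ])
  write_doc(doc, file)
}

#' @rdname write_corpus_xml
#' @param record A one-row corpus tibble.
#' @export
write_record <- function(record, file = NULL) {
  stopifnot(nrow(record) == 1)
  doc <- xml2::read_xml("<root/>")
  build_patient_node(doc, record)
  node <- xml2::xml_find_first(doc, "patient")
  patient_doc <- xml2::read_xml(as.character(node))
  write_doc(patient_doc, file)
}

# ---- JSON Lines convenience fixtures --------------------------------------

record_to_list <- function(rec) {
  sc <- function(x) if (is.na(x)) NULL else unname(x)
  docs <- rec$documents[[1]]
  compact(list(
    patient_id = rec$patient_id,
    first_name = sc(rec$first_name), middle_name = sc(rec$middle_name),
    last_name = sc(rec$last_name), nickname = sc(rec$nickname),
    date_of_birth = if (is.na(rec$date_of_birth)) NULL else format(rec$date_of_birth, "%Y-%m-%d"),
    nhs_number = sc(rec$nhs_number), trust_id = sc(rec$trust_id),
    phone_numbers = as.list(rec$phone_numbers[[1]]),
    addresses = purrr::transpose(as.list(rec$addresses[[1]])),
    key_contacts = purrr::transpose(as.list(rec$key_contacts[[1]])),
    documents = lapply(seq_len(nrow(docs)), function(i) {
      compact(list(
        doc_id = docs$doc_id[i], scope_id = docs$scope_id[i],
        date = if (is.na(docs$date[i])) NULL else format(docs$date[i], "%Y-%m-%d"),
        text = docs$text[i]
      ))
    })
  ))
}

#' Read and write corpora as JSON Lines
#'
#' One JSON object per line, using the same field names as the XML schema.
#'
#' @param records A corpus tibble.
#' @param file Path of the `.jsonl` file.
#' @return `write_corpus_jsonl()` returns `file` invisibly;
#'   `read_corpus_jsonl()` returns a corpus tibble.
#' @export
write_corpus_jsonl <- function(records, file) {
  assert_corpus(records)
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(record_to_list(records[i, ]), auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(file) {
  lines <- readLines(file, encoding = "UTF-8")
  lines <- lines[stri_trim_both(lines) != ""]
  if (length(lines) == 0) {
    return(source_record("template", "a", "b")[0, ])
  }
  out <- map_dfr(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    lst_tbl <- function(rows, cols) {
      if (length(rows) == 0) return(NULL)
      map_dfr(rows, function(r) {
        as_tibble(lapply(stats::setNames(cols, cols),
                         function(cc) r[[cc]] %||% NA_character_))
      })
    }
    addr <- lst_tbl(x$addresses, c("line1", "line2", "line3", "postcode", "status"))
    docs <- x$documents %||% list()
    documents <- if (length(docs) == 0) empty_documents() else {
      map_dfr(docs, function(d) {
        document(d$doc_id, d$scope_id, d$text, d$date %||% NA)
      })
    }
    source_record(
      patient_id = x$patient_id, first_name = x$first_name,
      middle_name = x$middle_name %||% NA, last_name = x$last_name,
      nickname = x$nickname %||% NA, date_of_birth = x$date_of_birth %||% NA,
      nhs_number = x$nhs_number %||% NA, trust_id = x$trust_id %||% NA,
      phone_numbers = unlist(x$phone_numbers) %||% character(),
      addresses = if (is.null(addr)) empty_addresses() else addr,
      key_contacts = lst_tbl(x$key_contacts, c("first_name", "last_name")) %||% empty_contacts(),
      documents = documents
    )
  })
  assert_corpus(out)
}
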