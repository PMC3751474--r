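# Free-text scanners. All spans are 0-based half-open character offsets into
# the original text. Each scanner emits candidate spans; resolve_spans()
# reconciles overlaps and mask_text() performs the replacement. Internals
# avoid per-match data-frame construction: a note is scanned thousands of
# times in a corpus run.

span_df <- function(start = integer(), end = integer(),
                    kind = character(), subject = character()) {
  tibble::new_tibble(
    list(start = as.integer(start), end = as.integer(end),
         kind = kind, subject = subject),
    nrow = length(start)
  )
}

empty_spans <- function() span_df()

dedup_spans <- function(df) {
  if (nrow(df) < 2) return(df)
  df[!duplicated(paste(df$start, df$end, df$kind, df$subject, sep = "\r")), ]
}

char_at <- function(text, pos0) {
  # character at 0-based position pos0; "" outside the text
  stri_sub(text, pos0 + 1, pos0 + 1)
}

is_alnum <- function(ch) {
  stri_detect_regex(ch, "^[\\p{L}\\p{N}]$") & !is.na(ch)
}

is_letter <- function(ch) {
  stri_detect_regex(ch, "^\\p{L}$") & !is.na(ch)
}

#' Token boundary test
#'
#' A candidate span is a token when (start rule) it begins the text or its
#' immediate prefix character is not a letter or digit, and (end rule) it
#' ends the text or its immediate suffix character is not a letter or digit.
#' Sentence-end punctuation (full stop, comma, colon, semicolon, hyphen) is a
#' valid suffix; being non-alphanumeric, it satisfies the end rule.
#'
#' @param text The text.
#' @param candidate_start,candidate_end 0-based half-open offsets
#'   (vectorized).
#' @return Logical vector.
#' @export
#' @examples
#' token_boundaries("7)Mark is", 2, 6)  # TRUE: prefix ")" is non-alphanumeric
#' token_boundaries("OMark is", 1, 5)   # FALSE: prefix "O" is a letter
token_boundaries <- function(text, candidate_start, candidate_end) {
  n <- stri_length(text)
  ok_start <- candidate_start <= 0 | !is_alnum(char_at(text, candidate_start - 1))
  ok_end <- candidate_end >= n | !is_alnum(char_at(text, candidate_end))
  ok_start & ok_end
}

# all case-insensitive fixed matches of each pattern; 0-based half-open,
# with the index of the matched pattern
locate_fixed0 <- function(text, patterns) {
  locs <- stri_locate_all_fixed(
    text, patterns,
    opts_fixed = stri_opts_fixed(case_insensitive = TRUE)
  )
  starts <- integer(); ends <- integer(); idx <- integer()
  for (i in seq_along(locs)) {
    m <- locs[[i]]
    if (is.na(m[1, 1])) next
    starts <- c(starts, m[, 1] - 1L)
    ends <- c(ends, m[, 2])
    idx <- c(idx, rep.int(i, nrow(m)))
  }
  list(start = starts, end = ends, pattern = idx)
}

#' Scan for dictionary names
#'
#' Finds case-insensitive occurrences of every name entry at valid token
#' boundaries. The span absorbs an immediately preceding letter+apostrophe
#' name delimiter ("O'Mark" masks whole) and an immediately following
#' possessive apostrophe-s ("Mark's" masks whole); absorption applies
#' whenever its extended span still sits at valid boundaries.
#'
#' @param text Text to scan.
#' @param dictionary A `cleaning_dictionary`.
#' @return Candidate span tibble (`start`, `end`, `kind`, `subject`).
#' @export
scan_names <- function(text, dictionary) {
  entries <- dictionary$entries[dictionary$entries$kind %in% c("name", "word_token"), ]
  if (nrow(entries) == 0) return(empty_spans())
  hits <- locate_fixed0(text, entries$surface)
  if (length(hits$start) == 0) return(empty_spans())
  n <- stri_length(text)

  s0 <- hits$start
  e0 <- hits$end
  # possessive suffix: apostrophe + s
  nxt1 <- char_at(text, e0); nxt2 <- char_at(text, e0 + 1)
  can_abs_end <- nxt1 %in% .apostrophes & stri_trans_tolower(nxt2) == "s"
  # name-delimiter prefix: letter + apostrophe
  prv1 <- char_at(text, s0 - 1); prv2 <- char_at(text, s0 - 2)
  can_abs_start <- s0 >= 2 & prv1 %in% .apostrophes & is_letter(prv2)

  end_abs_ok <- can_abs_end & (e0 + 2 >= n | !is_alnum(char_at(text, e0 + 2)))
  end_plain_ok <- e0 >= n | !is_alnum(nxt1)
  end_final <- ifelse(end_abs_ok, e0 + 2L, ifelse(end_plain_ok, e0, NA_integer_))

  start_abs_ok <- can_abs_start & (s0 - 2 <= 0 | !is_alnum(char_at(text, s0 - 3)))
  start_plain_ok <- s0 <= 0 | !is_alnum(prv1)
  start_final <- ifelse(start_abs_ok, s0 - 2L, ifelse(start_plain_ok, s0, NA_integer_))

  keep <- !is.na(start_final) & !is.na(end_final)
  if (!any(keep)) return(empty_spans())
  dedup_spans(span_df(
    start_final[keep], end_final[keep],
    entries$kind[hits$pattern[keep]], entries$subject[hits$pattern[keep]]
  ))
}

# two-digit years resolve to the century that lands closest to the patient's
# birth year (ties prefer 19xx)
resolve_year <- function(ystr, dob_year) {
  y <- suppressWarnings(as.integer(ystr))
  nc <- stri_length(ystr)
  if (is.na(y)) return(NA_integer_)
  if (nc == 4) return(y)
  if (nc != 2) return(NA_integer_)
  cands <- c(1900L + y, 2000L + y)
  cands[which.min(abs(cands - dob_year))]
}

valid_dmy <- function(d, m, y) {
  if (is.na(d) || is.na(m) || is.na(y)) return(FALSE)
  if (d < 1 || d > 31 || m < 1 || m > 12) return(FALSE)
  !is.na(as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d"))
}

# does any (day, month, year) reading of the three components equal dob?
# apo flags mark components written with a leading apostrophe ('01): such a
# component can only be a 2-digit year.
components_match_dob <- function(comps, apo, dob) {
  dob_d <- as.integer(format(dob, "%d"))
  dob_m <- as.integer(format(dob, "%m"))
  dob_y <- as.integer(format(dob, "%Y"))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    dstr <- comps[p[1]]; mstr <- comps[p[2]]; ystr <- comps[p[3]]
    if (any(apo[p[1:2]])) next                      # apostrophe only on the year
    if (apo[p[3]] && stri_length(ystr) != 2) next
    if (stri_length(dstr) > 2 || stri_length(mstr) > 2) next
    y <- resolve_year(ystr, dob_y)
    d <- suppressWarnings(as.integer(dstr))
    m <- suppressWarnings(as.integer(mstr))
    if (!valid_dmy(d, m, y)) next
    if (d == dob_d && m == dob_m && y == dob_y) return(TRUE)
  }
  FALSE
}

#' Scan for the patient's date of birth in numeric form
#'
#' Parses `<d><delim><m><delim><y>` triples (slash, dot or hyphen-dialect
#' delimiters, optional apostrophe before a 2-digit year) in any component
#' order that resolves to a valid calendar date, and masks the expression
#' only when it equals the patient's date of birth. A doubled delimiter
#' aborts the parse, so typographic errors are left untouched.
#'
#' @inheritParams scan_names
#' @return Candidate span tibble.
#' @export
scan_number_dates <- function(text, dictionary) {
  dob <- dictionary$canonical_dob
  if (is.null(dob)) return(empty_spans())
  if (!stri_detect_regex(text, "\\d")) return(empty_spans())
  delim <- "[./\\-–—]"
  apo <- paste0("[", paste(.apostrophes, collapse = ""), "]?")
  pat <- paste0("(\\d{1,4})", delim, "(", apo, ")(\\d{1,4})",
                delim, "(", apo, ")(\\d{1,4})")
  locs <- stri_locate_all_regex(text, pat)[[1]]
  if (is.na(locs[1, 1])) return(empty_spans())
  caps <- stri_match_all_regex(text, pat)[[1]]
  starts <- integer(); ends <- integer()
  for (i in seq_len(nrow(locs))) {
    comps <- caps[i, c(2, 4, 6)]
    apo_flags <- c(FALSE, caps[i, 3] != "", caps[i, 5] != "")
    if (!components_match_dob(comps, apo_flags, dob)) next
    s0 <- locs[i, 1] - 1L; e0 <- locs[i, 2]
    if (!token_boundaries(text, s0, e0)) next
    starts <- c(starts, s0); ends <- c(ends, e0)
  }
  span_df(starts, ends, rep.int("number_date", length(starts)),
          rep.int("patient", length(starts)))
}

month_number <- function(mword) {
  mword <- stri_trans_tolower(mword)
  m <- match(mword, stri_trans_tolower(.month_table$full))
  ifelse(is.na(m), match(mword, stri_trans_tolower(.month_table$abbrev)), m)
}

#' Scan for the patient's date of birth in word form
#'
#' Handles both component orders: day-first ("1st of January 2001",
#' "01 Jan 2001") and month-first ("Jan 1st 01"). Ordinal suffixes st/nd/rd/th
#' are accepted case-insensitively, with or without superscript carets; years
#' may be 4-digit, 2-digit or apostrophe-2-digit.
#'
#' @inheritParams scan_names
#' @return Candidate span tibble.
#' @export
scan_word_dates <- function(text, dictionary) {
  dob <- dictionary$canonical_dob
  if (is.null(dob)) return(empty_spans())
  if (!stri_detect_regex(text, "\\d")) return(empty_spans())
  months <- paste(c(.month_table$full, .month_table$abbrev), collapse = "|")
  apo <- paste0("[", paste(.apostrophes, collapse = ""), "]?")
  suffix <- "\\^?(?:st|nd|rd|th)?\\^?"
  yr <- paste0("(", apo, ")(\\d{4}|\\d{2})")
  p_day_first <- paste0(
    "(?i)(\\d{1,2})\\s*", suffix, "\\s*(?:of\\s+)?(", months, ")(?:\\s*,\\s*|\\s+)", yr
  )
  p_month_first <- paste0(
    "(?i)(", months, ")\\s+(\\d{1,2})\\s*", suffix, "(?:\\s*,\\s*|\\s+)", yr
  )
  dob_y <- as.integer(format(dob, "%Y"))
  dob_m <- as.integer(format(dob, "%m"))
  dob_d <- as.integer(format(dob, "%d"))
  starts <- integer(); ends <- integer()
  parse_hits <- function(pat, day_idx, month_idx) {
    locs <- stri_locate_all_regex(text, pat)[[1]]
    if (is.na(locs[1, 1])) return(invisible())
    caps <- stri_match_all_regex(text, pat)[[1]]
    for (i in seq_len(nrow(locs))) {
      d <- suppressWarnings(as.integer(caps[i, day_idx]))
      m <- month_number(caps[i, month_idx])
      y <- resolve_year(caps[i, 5], dob_y)
      if (!valid_dmy(d, m, y)) next
      if (!(d == dob_d && m == dob_m && y == dob_y)) next
      s0 <- locs[i, 1] - 1L; e0 <- locs[i, 2]
      if (!token_boundaries(text, s0, e0)) next
      starts <<- c(starts, s0); ends <<- c(ends, e0)
    }
    invisible()
  }
  parse_hits(p_day_first, day_idx = 2, month_idx = 3)
  parse_hits(p_month_first, day_idx = 3, month_idx = 2)
  dedup_spans(span_df(starts, ends, rep.int("word_date", length(starts)),
                      rep.int("patient", length(starts))))
}

#' Scan for the patient's own postcode
#'
#' Only the source postcode (spaced or unspaced form) is masked. The outward
#' code alone is never masked, and near-miss typographic variants do not
#' match.
#'
#' @inheritParams scan_names
#' @return Candidate span tibble.
#' @export
scan_postcodes <- function(text, dictionary) {
  pcs <- dictionary$canonical_postcodes
  if (length(pcs) == 0) return(empty_spans())
  variants <- unique(unlist(lapply(pcs, expand_postcode_variants)))
  hits <- locate_fixed0(text, variants)
  if (length(hits$start) == 0) return(empty_spans())
  ok <- token_boundaries(text, hits$start, hits$end)
  if (!any(ok)) return(empty_spans())
  dedup_spans(span_df(hits$start[ok], hits$end[ok],
                      rep.int("postcode", sum(ok)), rep.int("patient", sum(ok))))
}

#' Scan for the patient's phone, NHS and hospital ID numbers
#'
#' Candidate digit sequences written with spaces, dots, slashes,
#' hyphen-dialect delimiters or brackets around a group are normalized to
#' digits only and masked iff the digits equal one of the patient's canonical
#' phone numbers, NHS number or hospital (Trust) ID.
#'
#' @inheritParams scan_names
#' @return Candidate span tibble.
#' @export
scan_phones_ids <- function(text, dictionary) {
  canon <- c(
    stats::setNames(dictionary$canonical_phones,
                    rep("phone", length(dictionary$canonical_phones))),
    dictionary$canonical_ids
  )
  if (length(canon) == 0) return(empty_spans())
  if (!stri_detect_regex(text, "\\d")) return(empty_spans())
  run_pat <- "\\(?\\d+\\)?(?:[ \\t./\\-–—]\\(?\\d+\\)?)*"
  runs <- stri_locate_all_regex(text, run_pat)[[1]]
  if (is.na(runs[1, 1])) return(empty_spans())
  starts <- integer(); ends <- integer(); kinds <- character()
  for (r in seq_len(nrow(runs))) {
    run_s <- runs[r, 1]; run_e <- runs[r, 2]
    run_txt <- stri_sub(text, run_s, run_e)
    g <- stri_locate_all_regex(run_txt, "\\d+")[[1]]
    gs0 <- run_s - 1L + g[, 1] - 1L   # 0-based group starts in full text
    ge0 <- run_s - 1L + g[, 2]
    digits <- stri_sub(text, gs0 + 1, ge0)
    # bracketed group: "(" immediately before and ")" immediately after
    open <- char_at(text, gs0 - 1) == "(" & char_at(text, ge0) == ")"
    tok_s <- ifelse(open, gs0 - 1L, gs0)
    tok_e <- ifelse(open, ge0 + 1L, ge0)
    ng <- length(digits)
    for (i in seq_len(ng)) {
      for (j in i:ng) {
        val <- paste(digits[i:j], collapse = "")
        k <- match(val, canon)
        if (is.na(k)) next
        s0 <- tok_s[i]; e0 <- tok_e[j]
        if (!token_boundaries(text, s0, e0)) next
        starts <- c(starts, s0); ends <- c(ends, e0)
        kinds <- c(kinds, names(canon)[k])
      }
    }
  }
  dedup_spans(span_df(starts, ends, kinds, rep.int("patient", length(starts))))
}

#' Scan for address-term runs
#'
#' Text is tokenized on whitespace; a token counts as an address term when
#' its alphanumeric core (lowercased) is one of the patient's address terms
#' or alias forms. Maximal runs of two or more consecutive terms are masked
#' as one span; a lone generic term ("road") is never masked, and a run of
#' bare numbers carries no worded evidence and is skipped.
#'
#' @inheritParams scan_names
#' @return Candidate span tibble.
#' @export
scan_addresses <- function(text, dictionary) {
  terms <- dictionary$address_terms
  if (is.null(terms) || nrow(terms) == 0) return(empty_spans())
  toks <- stri_locate_all_regex(text, "\\S+")[[1]]
  if (is.na(toks[1, 1])) return(empty_spans())
  tok_txt <- stri_sub(text, toks[, 1], toks[, 2])
  flank <- stri_match_first_regex(
    tok_txt, "^([^\\p{L}\\p{N}]*+).*?([^\\p{L}\\p{N}]*)$"
  )
  lead <- stri_length(flank[, 2])
  trail <- stri_length(flank[, 3])
  trail[lead == stri_length(tok_txt)] <- 0L  # token is all punctuation
  core_s0 <- toks[, 1] - 1L + lead
  core_e0 <- toks[, 2] - trail
  core <- stri_trans_tolower(stri_sub(text, core_s0 + 1, core_e0))
  is_term <- core %in% terms$term & core_e0 > core_s0
  is_num_term <- is_term & core %in% terms$term[terms$is_number]

  runs <- rle(is_term)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  starts <- integer(); ends <- integer()
  for (r in which(runs$values)) {
    i <- idx_start[r]; j <- idx_end[r]
    if (j - i + 1 < 2) next
    if (all(is_num_term[i:j])) next   # numbers need a worded neighbour
    s0 <- core_s0[i]; e0 <- core_e0[j]
    if (!token_boundaries(text, s0, e0)) next
    starts <- c(starts, s0); ends <- c(ends, e0)
  }
  span_df(starts, ends, rep.int("address_term", length(starts)),
          rep.int("patient", length(starts)))
}

#' Resolve overlapping spans and mask the text
#'
#' Overlaps are resolved longest-span-first, ties broken leftmost, then
#' patient subject over relative. Each surviving span is replaced by the
#' masking string for its subject; text outside spans is untouched.
#'
#' @param text Original text.
#' @param spans Candidate spans from the scanners.
#' @param config A [scrub_config()].
#' @return `resolve_spans()`: the surviving spans with a `replacement`
#'   column; `mask_text()`: the masked text.
#' @export
resolve_spans <- function(spans, config = scrub_config()) {
  if (nrow(spans) == 0) {
    out <- empty_spans()
    out$replacement <- character()
    return(out)
  }
  ord <- order(-(spans$end - spans$start), spans$start, spans$subject != "patient",
               spans$kind)
  spans <- spans[ord, ]
  kept_start <- integer(); kept_end <- integer(); keep_row <- logical(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    if (!any(s < kept_end & e > kept_start)) {
      keep_row[i] <- TRUE
      kept_start <- c(kept_start, s); kept_end <- c(kept_end, e)
    }
  }
  out <- spans[keep_row, ]
  out <- out[order(out$start), ]
  out$replacement <- ifelse(out$subject == "relative",
                            config$mask_relative, config$mask_patient)
  out
}

#' @rdname resolve_spans
#' @export
mask_text <- function(text, spans, config = scrub_config()) {
  if (nrow(spans) == 0) return(text)
  if (!"replacement" %in% names(spans)) spans <- resolve_spans(spans, config)
  if (any(spans$end > stri_length(text)) || any(spans$start < 0)) {
    abort("internal error: span beyond text length")
  }
  ord <- order(-spans$start)
  for (i in ord) {
    stri_sub(text, spans$start[i] + 1, spans$end[i]) <- spans$replacement[i]
  }
  text
}

#' Scrub one text against a cleaning dictionary
#'
#' Runs the configured scanners, resolves overlaps, and replaces every
#' surviving span with ZZZZZ (patient) or QQQQQ (relative / close contact).
#' Scrubbing is idempotent: the masking strings match no scanner.
#'
#' @param text Text to scrub (`NA` passes through).
#' @param dictionary A `cleaning_dictionary` for the patient the text
#'   belongs to.
#' @param config A [scrub_config()].
#' @return A list with `text` (masked) and `spans` (resolved spans on
#'   original-text coordinates).
#' @export
#' @examples
#' rec <- source_record("p1", "Mark", "Dunn")
#' scrub_text("knowing Mark's diagnosis", build_dictionary(rec))$text
scrub_text <- function(text, dictionary, config = scrub_config()) {
  if (length(text) != 1 || is.na(text) || text == "") {
    out <- empty_spans()
    out$replacement <- character()
    return(list(text = text, spans = out))
  }
  scanners <- list(
    names = scan_names, number_dates = scan_number_dates,
    word_dates = scan_word_dates, postcodes = scan_postcodes,
    phones_ids = scan_phones_ids, addresses = scan_addresses
  )
  pieces <- lapply(config$scanners, function(s) scanners[[s]](text, dictionary))
  pieces <- pieces[vapply(pieces, nrow, integer(1)) > 0]
  spans <- if (length(pieces) == 0) {
    empty_spans()
  } else {
    span_df(
      unlist(lapply(pieces, `[[`, "start")),
      unlist(lapply(pieces, `[[`, "end")),
      unlist(lapply(pieces, `[[`, "kind")),
      unlist(lapply(pieces, `[[`, "subject"))
    )
  }
  resolved <- resolve_spans(spans, config)
  list(text = mask_text(text, resolved, config), spans = resolved)
}
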