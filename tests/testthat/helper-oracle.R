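# Independent brute-force name matcher: tests every substring of the text
# against every dictionary entry, applying the token-boundary and absorption
# rules position by position. Deliberately naive and written separately from
# the scanner implementation.

apos <- c("'", "’", "‘", "ʼ")

brute_is_alnum <- function(ch) length(ch) == 1 && grepl("^[[:alnum:]]$", ch)
brute_is_letter <- function(ch) length(ch) == 1 && grepl("^[[:alpha:]]$", ch)

brute_name_spans <- function(text, entries) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  low <- tolower(text)
  out <- list()
  for (k in seq_len(nrow(entries))) {
    surf <- entries$surface[k]
    len <- nchar(surf)
    if (len > n) next
    for (s0 in 0:(n - len)) {
      if (substr(low, s0 + 1, s0 + len) != surf) next
      e0 <- s0 + len
      # end: prefer absorbing apostrophe+s when the extended end is a boundary
      end_final <- NA_integer_
      if (e0 + 2 <= n && chars[e0 + 1] %in% apos && tolower(chars[e0 + 2]) == "s" &&
          (e0 + 2 == n || !brute_is_alnum(chars[e0 + 3]))) {
        end_final <- e0 + 2L
      } else if (e0 == n || !brute_is_alnum(chars[e0 + 1])) {
        end_final <- e0
      }
      # start: prefer absorbing letter+apostrophe when the extended start works
      start_final <- NA_integer_
      if (s0 >= 2 && chars[s0] %in% apos && brute_is_letter(chars[s0 - 1]) &&
          (s0 - 2 == 0 || !brute_is_alnum(chars[s0 - 2]))) {
        start_final <- s0 - 2L
      } else if (s0 == 0 || !brute_is_alnum(chars[s0])) {
        start_final <- s0
      }
      if (is.na(start_final) || is.na(end_final)) next
      out[[length(out) + 1]] <- data.frame(
        start = start_final, end = end_final,
        kind = entries$kind[k], subject = entries$subject[k],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else {
    data.frame(start = integer(), end = integer(), kind = character(),
               subject = character(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$start, res$end, res$kind, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# a fake dictionary holding only literal name entries, for scanner tests
name_only_dict <- function(surfaces, subjects = rep("patient", length(surfaces))) {
  structure(
    list(
      patient_id = "T",
      entries = tibble::tibble(surface = tolower(surfaces), kind = "name",
                               subject = subjects),
      canonical_dob = NULL, canonical_phones = character(),
      canonical_ids = character(), canonical_postcodes = character(),
      address_terms = tibble::tibble(term = character(), is_number = logical())
    ),
    class = "cleaning_dictionary"
  )
}

# random text built from dictionary words, near-words and punctuation
random_name_text <- function(entries, max_len = 500) {
  word_pool <- c(
    entries, paste0(entries, "x"), paste0("x", entries),
    replicate(8, paste(sample(letters, sample(2:7, 1), replace = TRUE), collapse = ""))
  )
  seps <- c(" ", " ", " ", ")", ".", ", ", "\n", "; ", "")
  deco <- function(w) {
    r <- runif(1)
    if (r < 0.15) paste0(w, "'s")
    else if (r < 0.25) paste0("O'", w)
    else if (r < 0.35) toupper(w)
    else if (r < 0.5) paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    else w
  }
  txt <- ""
  while (nchar(txt) < max_len) {
    w <- deco(sample(word_pool, 1))
    txt <- paste0(txt, w, sample(seps, 1))
    if (runif(1) < 0.1) break
  }
  substr(txt, 1, max_len)
}

sorted_spans <- function(df) {
  df <- as.data.frame(df[, c("start", "end", "kind", "subject")])
  df <- unique(df)
  df <- df[order(df$start, df$end, df$kind, df$subject), , drop = FALSE]
  rownames(df) <- NULL
  df
}
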