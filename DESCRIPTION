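Package: deidr
Title: Dictionary-Based De-Identification of Electronic Health Record Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De-identifies per-patient electronic health records by building a
    patient-specific cleaning dictionary from structured identifier fields
    (names, date of birth, NHS and hospital numbers, telephone numbers,
    addresses and postcodes, key contacts), expanding each identifier into its
    recognised surface variants, and scanning configured free-text scopes for
    matches under token-boundary rules. Matched patient identifiers are masked
    with a constant string (ZZZZZ), relative and close-contact identifiers with
    QQQQQ; structured fields are stripped or weakened (postcode outward code,
    month and year of birth). Includes a synthetic patient-record generator
    with gold-standard identifier spans, and an evaluation harness computing
    precision, recall, residual-identifier tables and a potential-breach audit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringi,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
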