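# deidr

Dictionary-based de-identification of electronic health record (EHR) text,
for research databases built from clinical records without patient-level
consent. `deidr` is aimed at health-informatics teams and researchers who
need to mask patient identifiers (PIs) in free-text notes *and* apply a
strip/weaken policy to structured fields, and at methodologists who want to
study how far a purely dictionary-driven scrubber can go.

## The method

For each patient, a **cleaning dictionary** is built from that patient's own
structured fields — never from population registries. Each identifier is
expanded into its recognised surface variants:

| field | example | variants |
|---|---|---|
| names | `O'Connell` | delimiter-stripped tokens (`connell`) |
| date of birth | `1987-08-20` | `20/08/1987`, `20.8.87`, `20th of August 1987`, ... |
| hospital / NHS IDs | `12-34-56` | `12-34-56`, `123456`, `12 34 56` |
| phone numbers | `02071234567` | `(020) 7123 4567`, `0207 123 4567`, ... |
| postcode | `SW9 6TJ` | `SW9 6TJ`, `SW96TJ` |
| address lines | `12 Acacia Road` | `12`, `acacia`, `road`, `rd` (alias-closed) |

The scrubber scans only configured free-text *scopes*. A candidate token
matches when its prefix is not a letter/digit (or starts the line) and its
suffix is not a letter/digit (or ends the sentence: `. , : ; -`). Dates and
numbers are matched by *parse-then-compare* against the canonical values, so
`01-01-'01`, `Jan 1st 01` and `(00000) 000 000` all resolve. Matches are
replaced by the constant masks **ZZZZZ** (patient) and **QQQQQ**
(relative/close contact). Structured fields are then stripped entirely
(names, IDs, phones, address lines), truncated (postcode → outward code,
`SW9 6TJ` → `SW9`) or weakened (date of birth → month + year).

Evaluation follows the standard span-level protocol: precision
`tp / (tp + fp)` and recall `tp / (tp + fn)` over gold spans, where
misspelt and identifiers never entered in the structured fields are designed
misses, reported in a residual table; the **potential-breach audit** flags
any patient with ≥ 3 residual identifiers in one note or across their note
series. Because real corpora for this task are confidential, the package
includes a synthetic patient-record generator with gold-standard spans
covering the full variant grammar plus controlled misspelling/un-entered
rates.

## Worked example

```r
library(deidr)

rec <- source_record("p1", "Joe", "Bloggs", date_of_birth = "1987-08-20",
  trust_id = "12-34-56",
  addresses = address("12 Acacia Road", postcode = "SW9 6TJ"),
  key_contacts = tibble::tibble(first_name = NA, last_name = "O'Connell"),
  documents = document("d1", "event_note",
    "Joe (dob 20.8.87) seen at 12 Acacia Rd. Discussed O'Connell's visit. ID 12 34 56."))

out <- deidentify(rec, secret = "demo")
out$records$documents[[1]]$text
#> ZZZZZ (dob ZZZZZ) seen at ZZZZZ. Discussed QQQQQ visit. ID ZZZZZ.

tidy(out)   # audit spans (offsets and kinds only - surfaces are never logged)
#> # A tibble: 5 × 7
#>   patient_id doc_id start   end kind         subject  replacement
#> 1 p1         d1         0     3 name         patient  ZZZZZ
#> 2 p1         d1         9    16 number_date  patient  ZZZZZ
#> 3 p1         d1        26    38 address_term patient  ZZZZZ
#> 4 p1         d1        50    61 name         relative QQQQQ
#> 5 p1         d1        72    80 trust_id     patient  ZZZZZ
```

Every identifier was caught in a different written form than the structured
field held (`20.8.87` for the date, `Acacia Rd` for the address, `12 34 56`
for the ID); the relative's name got the distinct `QQQQQ` mask; the
de-identified record keeps only month/year of birth (`8`, `1987`) and the
postcode outward code (`SW9`).

Synthetic evaluation end to end:

```r
gc <- generate_corpus(200, corruption_profile(seed = 1))
ev <- evaluate_corpus(gc$records, gc$gold)
glance(ev$eval)       # precision/recall over clean gold spans
residual_table(ev$eval)  # unmasked misspelt / un-entered instances by type
autoplot(ev$eval)     # per-kind recall
```

A command-line wrapper ships at `inst/cli/scrub.R`
(`scrub run | dict | eval`), and records interchange as per-patient XML or
JSON Lines (schema in `inst/extdata/record-schema.md`).

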