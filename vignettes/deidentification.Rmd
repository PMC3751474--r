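---
title: "Dictionary-based de-identification of clinical free text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary-based de-identification of clinical free text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deidr)
```

## The problem and the model

Electronic health records mix structured identifier fields (names, date of
birth, NHS and hospital numbers, telephone numbers, addresses) with free-text
notes in which the same identifiers reappear in many written forms. To make
such records usable for research without consent, every patient identifier
(PI) must be removed or degraded — and free text is where this is hard.

`deidr` implements a *dictionary-driven* approach. For each patient, a
cleaning dictionary is built **from that patient's own structured fields**,
not from population registries: each identifier is expanded into the surface
variants it can plausibly take in text (a date of birth becomes `20/08/1987`,
`20.8.87`, `20th of August 1987`, ...; a phone number becomes its standard UK
groupings; a postcode its spaced and unspaced forms; names are stripped of
apostrophes and hyphens and entered token-wise). The scrubber then scans only
the configured free-text *scopes*, matching candidates against the dictionary
under token-boundary rules, and replaces matches with a constant masking
string — `ZZZZZ` for the patient's own identifiers, `QQQQQ` for relatives and
close contacts. Constant masks are used instead of category labels because
the surrounding context usually reveals the category anyway; a constant
string adds no information.

The approach rests on one empirical assumption: the structured PI fields are
populated nearly always (names are mandatory; date of birth and address
coverage in a large source system run at roughly 99.7% and 98.5%). What is
not entered in those fields — and what is misspelt in them — is *by design*
not recognised in text. The surrounding governance model, not the algorithm,
carries that residual risk; this package implements and measures the
algorithmic part only.

## Matching rules

**Token boundaries.** A candidate match is accepted only when its immediate
prefix is not a letter or digit (or it starts the text/line) and its
immediate suffix is not a letter or digit (or it ends the text; sentence
punctuation `. , : ; -` is an ordinary non-alphanumeric suffix). So `Mark`
is masked in `7)Mark` but not in `OMark`.

**Names.** Dictionary name tokens are matched case-insensitively. The span
absorbs a preceding letter-plus-apostrophe delimiter (`O'Mark` masks whole)
and a trailing possessive (`Mark's` masks whole) whenever the extended span
still sits on valid boundaries; a trailing comma or full stop stays outside
the span. Matching is deliberately literal: the common word *mark* is masked
alongside the name *Mark* (over-masking is accepted), while the misspelling
*Marik* is not masked at all.

**Dates.** Numeric dates are parsed, not looked up: any
`<d><delim><m><delim><y>` triple with a single slash, dot or hyphen-dialect
delimiter (and an optional apostrophe before a two-digit year) is resolved
in every component order that yields a valid calendar date and masked only
when it equals the patient's date of birth. A doubled delimiter
(`01//01/2001`) aborts the parse. Word dates are handled in both orders
(`1st of January 2001`, `Jan 1st 01`), with ordinal suffixes accepted with
or without superscript markers. The literal variant strings are still
emitted into the dictionary for dumps and cross-checks; scanning goes
through the parser so that variants the expansion does not enumerate (e.g.
`2001/01/01`) are caught too.

**Numbers.** Digit sequences written with spaces, dots, slashes, hyphens or
brackets are normalized to digits and masked iff equal to a canonical phone,
NHS or hospital-ID number of this patient. **Postcodes** match only the
patient's own postcode, spaced or unspaced — the outward code alone is never
masked, and a transposition (`EN1 S5R`) does not match. **Addresses** mask
maximal runs of two or more consecutive address terms, where alias forms
(road/rd, street/st, ...) count as the same term; a lone generic word
("road") is never masked, and a bare house number only counts adjacent to a
worded term of the same patient — masking every isolated "12" would destroy
the text for no identification gain.

**Overlaps** are resolved longest-span-first, ties leftmost, patient subject
over relative. This rule is plumbing of this implementation; any fixed rule
would do, but one is needed for determinism.

## Numerical and dialect choices

* Hyphen, en-dash and em-dash are treated as one delimiter character, and
  straight and curly apostrophes as one apostrophe: clinical text and the
  source fields mix them freely. Dictionary literals are stored in the ASCII
  dialect, lowercase.
* Two-digit years resolve to the century that lands closest to the patient's
  birth year (ties prefer 19xx). Only the comparison against the known date
  of birth makes two-digit years usable at all.
* Single-character name fragments produced by delimiter stripping (the "O"
  of `O'Connell`) are dropped from the dictionary — a one-letter entry would
  mass-over-mask.
* An empty structured field is treated as absent and contributes nothing.
* Masking is idempotent: `ZZZZZ`/`QQQQQ` match no scanner, so re-scrubbing
  output is the identity.
* The per-record pseudonymous identifier is a keyed hash of the patient id
  whose key is run-scoped and discarded, so the de-identified output retains
  no linkage; supply `secret =` to `deidentify()` when byte-identical reruns
  are needed.

Where the interchange format was undocumented, this package defines its own
per-patient XML schema mirroring the described hierarchy (see
`inst/extdata/record-schema.md`), plus a JSON Lines dialect for fixtures.
The address alias table ships as editable YAML; only the road/rd and
street/st pairs are given canonically, the remaining street-type groups are
this package's stated extension. Structured fields beyond date of birth and
postcode that a deployment may want weakened (ethnicity and similar) pass
through by default, with the policy map as the hook; month-plus-year is the
default date-of-birth weakening, matching standard UK practice for weak
identifiers.

## The synthetic corpus: what it emulates, and what it does not

Real evaluation corpora for this task are confidential, so the package
ships a generator (`generate_corpus()`) producing fictitious patients with
gold-standard spans. It emulates the *statistical structure the algorithm
cares about*: near-complete structured-field coverage (date of birth 99.7%,
address 98.5% by default), identifier mentions drawn across the full variant
grammar (all date shapes, phone groupings, possessives, O'-prefixes,
line-initial and bracketed contexts), ambiguous common-word names (mark,
summer) to exercise over-masking, and the two designed failure classes:

* **misspelt** mentions — perturbed at edit distance one, re-drawn (or, as a
  last resort, wounded in every token) until genuinely uncatchable, so their
  gold status is truthful;
* **un-entered** mentions — nicknames and old addresses that appear in text
  but not in the structured fields.

The default corruption profile (`p_misspell = 0.15`, `p_unentered = 0.05`)
yields a residual pool of roughly three misspellings per un-entered
identifier, mirroring the mix reported for real clinical notes. The
generator does **not** model realistic clinical language: fillers are
neutral sentences, deliberately free of digits, month words and wordlist
names. Consequently, a perfect score on a clean synthetic corpus shows that
the scanner grammar and the generator grammar agree exactly — it bounds
implementation errors, not real-world performance, where spelling noise,
unanticipated formats and un-entered identifiers dominate the residual risk.

## Evaluation and the breach audit

`score_spans()` matches emitted and gold spans by exact offsets on
original-text coordinates. Headline precision and recall are computed over
*clean* gold spans only; misspelt and un-entered instances are designed
misses and are reported in the residual table instead (patient- and
relative-subject masks are additionally broken out, since whether relative
masks belong in the headline is a reporting choice). `audit_breaches()`
implements the three-or-more rule: a potential breach is any patient with at
least three residual true-or-apparent identifiers in a single note, or
across their note series; duplicate mentions of one value count once per
note, because the rule concerns distinct identifying facts. All residual
kinds count as "strong potential" identifiers — the conservative reading.

## Problem sizes and test design

The package's own checks run at sizes chosen to give stable statistics on a
single CPU: the soundness sweep and the acceptance script use 200 patients
with 5 notes each (1,000 notes, roughly 1,600-2,000 identifier mentions);
the idempotence suite re-scrubs 1,000 notes; the brute-force scanner oracle
compares 500 random texts of up to 500 characters against dictionaries of up
to 20 entries. Generation is fully reproducible from the profile seed.

## Known limitations

* Misspelt and un-entered identifiers are not masked — fidelity to the
  design, not an oversight. Deployments must pair the algorithm with access
  governance.
* Common words identical to patient names are over-masked; no context
  disambiguation is attempted.
* Clinician and staff names are not masked (no dictionary source for them,
  and no legal requirement in the modelled setting).
* The phone grammar covers 10-11 digit UK-style numbers; other national
  formats would need new groupings.
* The breach audit sees only what the gold annotation labels as residual;
  on real data the equivalent step is a manual scan.
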