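# Interchangeable address words: each group lists surface forms of one term.
# The first two pairs are standard UK-address abbreviations; the remainder
# extend the same pattern to the other common street-type words.
- [road, rd]
- [street, st]
- [avenue, ave]
- [close, cl]
- [lane, ln]
- [court, ct]
- [drive, dr]
- [gardens, gdns]
- [square, sq]
- [place, pl]
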