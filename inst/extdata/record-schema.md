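# Per-patient XML record schema

One `<patient>` element per patient; a `<corpus>` root may wrap several.
Encoding is UTF-8. Absent fields are absent elements — never empty strings.
Text inside `<document>` is verbatim: character offsets (0-based, half-open)
into it are stable across read/write.

```
<corpus>
  <patient id="P0001">
    <identifiers>
      <first_name>Joe</first_name>          (mandatory)
      <middle_name>...</middle_name>        (optional)
      <last_name>Bloggs</last_name>         (mandatory)
      <nickname>...</nickname>              (optional; alias/former name)
      <date_of_birth>1987-08-20</date_of_birth>
      <nhs_number>1234567890</nhs_number>
      <trust_id>12-34-56</trust_id>
      <phone_numbers>
        <phone>07123456789</phone>
      </phone_numbers>
      <addresses>
        <address status="current|old">
          <line1>12 Acacia Road</line1>
          <line2>...</line2>
          <line3>...</line3>
          <postcode>SW9 6TJ</postcode>
        </address>
      </addresses>
      <key_contacts>
        <key_contact>
          <first_name>...</first_name>
          <last_name>O'Connell</last_name>
        </key_contact>
      </key_contacts>
    </identifiers>
    <documents>
      <document id="P0001-D01" scope="event_note" date="2012-04-02">free text</document>
    </documents>
  </patient>
</corpus>
```

Scopes are free-text field names (`summary`, `event_note`, `correspondence`,
`ward_progress` by default); only documents whose scope is configured are
scrubbed.

A JSON Lines dialect with identical field names is also supported
(one patient object per line).
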