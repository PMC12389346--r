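# Packaged curated dataset

Plain-text transcription of a literature-curated stability dataset of
compounded oral solid preparations, drawn from the public *Stabilis* drug
stability database together with hospital compounding records, plus the
molecular descriptors of the active pharmaceutical ingredients (APIs) and
excipients involved (descriptors originally retrieved from ChEMBL / PubChem).

Files

- `stability_records.csv` — 53 stability observations: API, one or two
  excipients, packaging (`G` glass, `Pl` plastic, `P` paper, `ND` not
  documented), dose (mg), API content (% of unit-dose mass), storage
  temperature (deg C), and the experimental beyond-use date (BUD) in days.
  The sentinel `-` marks a missing value; `ND` marks an undocumented one.
- `api_descriptors.csv` — the 22 APIs with molecular weight (g/mol), LogP,
  rotatable bonds, polar surface area (A^2), H-bond donor/acceptor counts and
  aromatic-ring count. The `mc_printed` / `msc_printed` columns carry the
  composite molecule class (MC) and molecular structure class (MSC) values as
  printed in the original curation; they are stored for reference only and
  are never trusted as computed values (see `class_delta_report()`).
- `excipients.csv` — the six excipients with the same seven descriptors,
  functional roles, predominant solid form, and manufacturer shelf life in
  years.

Notes

- The SMILES strings are opaque identifiers in this package (they are only
  ever label-encoded, never parsed); they were filled in from public
  structure databases as a best effort.
- The original curation narrative mentions 55 stability points over 23 APIs,
  but only 53 records covering 22 APIs are tabulated anywhere; the two
  unprinted records cannot be reconstructed, so this transcription carries
  exactly 53 records and 22 APIs.
- Two conditioning entries printed as `PI` were read as a typesetting error
  for `Pl` (plastic) and transcribed as such.
- For several APIs the printed MC/MSC disagree by 1-3 units with any single
  consistent binning convention; `class_delta_report()` lists the
  computed-versus-printed deltas rather than guessing per-row intent.
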