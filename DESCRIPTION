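Package: lnaclamp
Title: Design of LNA Primers and PCR-Clamping Oligonucleotides for Fungal
    ITS Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for suppressing host-plant amplification in fungal
    internal transcribed spacer (ITS) amplicon surveys. Builds degenerate
    fungus-specific forward primers from alignment column profiles, plans
    locked nucleic acid (LNA) substitutions at fungus-discriminating
    positions, designs host-blocking LNA clamp oligonucleotides that compete
    with the reverse primer (3'-phosphorylated, one- or two-base overlap),
    predicts melting temperatures with an LNA-aware nearest-neighbor model,
    screens clamps for cross-reactivity against fungal sequences, and emits
    clamped-PCR thermal programs, titration series, and DGGE-ready nested
    primers. Includes a seeded synthetic alignment generator so every design
    stage is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
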