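Package: nr2dbd
Title: Motif-Grammar Annotation and Classification of Nuclear Receptors
    with Two DNA-Binding Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects tandem C4 zinc-finger DNA-binding domains (DBDs) in
    protein sequences, extracts the P-box and D-box, measures the inter-DBD
    linker, and annotates the C-terminal extension (G-box, pre-Grip, T-box),
    the N-terminal signature sequence (NTSS), and ligand-binding-domain
    signatures (Ti, AF2-AD core, class I/II dimerization residues). Sequences
    with the two-DBD architecture (2DBD-NRs) are classified into groups A, B
    and C from their P-P module and named under a rule-based nomenclature.
    Includes a seeded synthetic-sequence generator with ground truth for
    round-trip validation and a neighbor-joining corroborator over DBD
    regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
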