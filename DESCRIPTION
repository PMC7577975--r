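Package: mirduplex
Title: Positional Sequence Analysis of Plant miRNA Precursor Foldbacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to survey sequence and structure features of plant
    microRNA precursors. Registers the two arms of an imperfect foldback
    into a duplex alignment anchored at the DCL1 cleavage sites, infers the
    miRNA* from the 2-nt 3' overhang geometry, classifies base-pair
    identities (Watson-Crick, G-U wobble, mismatch, bulge) per position,
    aggregates position-wise pair-frequency matrices against a
    mononucleotide independence null, scores candidate artificial miRNA
    precursors against empirically derived mismatch-identity rules, and
    generates synthetic precursors with planted ground truth for
    validation. Secondary structures are parsed from Vienna dot-bracket
    notation or predicted with an external minimum-free-energy folding
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
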