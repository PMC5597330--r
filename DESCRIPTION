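Package: codonharmony
Title: Codon Usage Tables, Harmonization and Adaptation Metrics for
    Heterologous Gene Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds codon usage tables from complete CDS collections of a
    genome and converts them to relative codon adaptiveness (RCA) scores.
    Scores coding sequences with the codon adaptation index (CAI) and a
    codon harmonization index (CHI), profiles per-codon RCA landscapes
    with a sliding-window average, and recodes genes so that their codon
    landscape in an expression host mimics the wild-type landscape in the
    native host, optionally removing restriction-enzyme motifs by
    next-closest synonymous substitutions.  Includes a transparent
    most-frequent-codon recoder as an optimization baseline, a seeded
    synthetic-host generator for testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
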