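Package: guidekit
Title: CRISPR Cas9/Cas12a Guide Design, GoldenGate Assembly Planning and
    Editing Outcome Analysis for Barley and Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Companion toolkit for a modular GoldenGate (MoClo-style) CRISPR
    mutagenesis system for barley and wheat. Scans target sequences for Cas9
    (NGG) and Cas12a (TTTV) sites, emits cloning-ready oligonucleotide pairs
    with architecture-specific overhangs, selects binary vectors and produces
    ordered level 1 / level M / level 2 cloning plans, verifies plans by
    simulating type-IIS digestion-ligation in silico, quantifies editing
    outcomes from aligned amplicon read pairs (modal-start filtering, CIGAR
    indel-pattern extraction, percent wild-type reporting) and from Sanger
    reads, and reproduces the associated efficiency statistics (binomial GLM
    likelihood-ratio tests, crossed ANOVA, per-construct summaries, all-target
    rates and synergy decomposition). Includes seed-deterministic simulators
    for amplicon read pairs and T0 editing cohorts so every component is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    utils
Suggests:
    GenomicAlignments,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
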