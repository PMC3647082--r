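Package: comigr
Title: Protein Co-Migration Profiling from Blue Native PAGE Complexome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds emPAI-based protein migration profiles from per-gel-slice
    peptide identifications produced by blue native PAGE coupled with
    LC-MS/MS, detects profile peaks, estimates native complex masses from a
    marker calibration curve, infers co-migrating protein groups as candidate
    protein complexes, and exports database-style per-protein records.
    Includes in-silico tryptic digestion with observable-peptide counting
    (the emPAI denominator), annotation summaries (localization, functional
    category, genome coverage), and a synthetic-data generator that emulates
    complexes migrating as Gaussian peaks with abundance-dependent,
    hydrophobicity-attenuated peptide detection, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
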