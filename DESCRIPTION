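Package: goldalign
Title: Heuristic-Free Optimal Read Alignment to Linear and Variation-Graph References
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Exhaustive affine-gap dynamic-programming alignment of short reads to a
    linear reference or to a directed acyclic variation graph built from a reference
    FASTA and a VCF, with semiglobal and local modes, quality-scaled mismatch
    penalties and aligner-mimicking scoring presets. Because no heuristics are used,
    the reported scores are guaranteed optima and serve as a computational gold
    standard for auditing heuristic read aligners: the package includes
    correct-by-score and correct-by-location evaluation, score-binned accuracy
    summaries, mapping-quality (MAPQ) calibration reports and parameter-sweep ratio
    tables, plus a synthetic-data generator and a path-enumeration alignment oracle
    used to verify the aligner itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
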