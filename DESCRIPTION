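Package: genestats
Title: Relational Gene Structure Statistics from Genome Annotation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses genome annotation (GFF3 or a three-table tab-delimited
    dialect) into a relational gene/transcript/exon-intron model, derives
    per-transcript and per-gene structure features (gene spans, mature mRNA,
    CDS and UTR lengths, exon and intron counts), builds non-redundant exon,
    coding-exon and intron sets across transcript isoforms, classifies
    splice-site dinucleotides from chromosome sequences, and computes dynamic
    summary statistics (median, mean, SD, total, extremes with record
    identity) over arbitrarily filtered subsets. Includes a command-line
    interface, a deterministic synthetic-annotation generator with a truth
    manifest for validation, and published reference totals for the human
    nuclear gene set.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
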