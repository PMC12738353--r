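Package: isomirdiv
Title: IsomiR Diversity Analysis for Small RNA-Seq with Survival and
    Target-Site Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing microRNA isoform (isomiR) diversity in
    small RNA-seq read-count tables. Names isomiRs by signed 5'/3' terminal
    offsets relative to the archetype mature sequence, filters low-abundance
    isoforms, computes per-miRNA per-sample isoform-diversity matrices,
    tabulates pooled isoform-count categories, tests diversity differences
    between tissue or histology groups, stratifies event-free survival by
    diversity or expression groups (Kaplan-Meier, log-rank, Cox), scans
    3'UTR sequences for seed-complementary sites with mismatch tolerance
    and an extended-duplex pairing score, and quantifies
    immunohistochemistry readouts (IRS and H-score). A seeded synthetic-data
    generator produces count tables, clinical tables, precursor/mature
    annotations and UTR sequences with planted signal so the whole pipeline
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    methods,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
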