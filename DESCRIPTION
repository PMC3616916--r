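Package: orphanest
Title: Partitioning Orphan Transcripts in EST Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the unannotated ("orphan") fraction of an
    assembled EST collection and partitioning it among four explanatory
    sources: sequence quality (ORF length, start codons, GC content),
    assembly failure (a single-copy-ortholog duplication statistic with an
    adjusted unique-gene count), lack of function (expression calling
    against a random-probe empirical null), and taxonomic isolation
    (homology partitioning across reference datasets with a
    reference-completeness discount correction), plus a gene-family
    exclusivity resampling test and a stepwise accounting ledger. A seeded
    synthetic-data module emulates every input with known ground truth so
    the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
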