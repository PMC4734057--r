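Package: alnkit
Title: Manipulation and Summary Statistics for Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reads and writes multiple sequence alignments in FASTA, PHYLIP
    (sequential and interleaved) and NEXUS (sequential and interleaved)
    dialects, concatenates single-locus alignments into supermatrices with
    partition bookkeeping, splits supermatrices by partition schemes, builds
    randomized jackknife replicate datasets, removes taxa, converts among
    formats in parallel batches, and computes per-alignment summary
    statistics including missing data, base composition and counts of
    variable and parsimony-informative sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    parallel,
    stats,
    tools,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
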