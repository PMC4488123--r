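Package: epifpca
Title: Functional Principal Component Analysis of Genomic Coverage Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes next-generation-sequencing coverage profiles around
    anchored genomic regions (e.g. transcription start sites) into functional
    principal components, a finite Karhunen-Loeve transform realised through a
    B-spline basis expansion. Provides readers for bedGraph coverage tracks and
    BED region files, wigsum normalization, blacklist filtering,
    strand-oriented profile extraction, the FPCA eigenproblem in basis
    coordinates, and a two-coefficient cross-dataset correlation scheme that
    separates co-localization of variability (eigenfunction correlation) from
    co-variation of signal (score correlation), with Bonferroni-corrected
    significance tests, gene-expression association, and a synthetic-data
    generator with planted Karhunen-Loeve structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    pracma,
    jsonlite,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
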