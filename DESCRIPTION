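Package: karyomosaic
Title: Single-Cell Karyotype Analysis and Chromosomal Mosaicism Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-cell whole-genome copy-number data from human
    blastocysts: quality control of binned read-count profiles (read depth,
    spikiness, Bhattacharyya separation), divisive copy-number calling,
    cataloguing of numerical and structural chromosomal abnormalities,
    embryo-level classification of chromosomal mosaicism, inference of
    meiotic versus mitotic origin, grouping of abnormalities into mitotic
    segregation-error events with timing relative to trophectoderm/inner-cell-mass
    lineage specification and mechanism labels, and an in-silico bulk DNA-Seq
    comparison quantifying what a multicellular biopsy would detect. A
    blastocyst simulator with explicit division trees and ground-truth event
    logs drives validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
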