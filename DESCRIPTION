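Package: sarmatrix
Title: SAR Matrices from Two-Level Matched Molecular Pair Fragmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts structurally analogous matched molecular series from
    compound collections by systematic two-level matched-molecular-pair
    (MMP) fragmentation and organizes them into structure-activity
    relationship (SAR) matrices of analog-series rows and substituent
    columns with real and virtual cells. Matrices are scored and ranked by
    overlap, coverage, SAR continuity and discontinuity, activity cliffs
    and SAR-transfer events; potencies of virtual compounds are predicted
    by Free-Wilson neighborhood additivity with consistency assessment over
    multiple neighborhoods; multi-target activity annotations are handled
    through compound-series matrices with promiscuity profiles and
    single-target deconvolution. Includes a synthetic combinatorial library
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
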