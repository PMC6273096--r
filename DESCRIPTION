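Package: efgtools
Title: Extended Functional Group Profiling and Enrichment Analysis for Small Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A curated registry of 583 extended functional group (EFG) definitions
    encoded as SMARTS patterns -- classical functional group families, a systematic
    high-/low-specificity heterocycle taxonomy, and periodic-table element
    categories -- together with an aromaticity-normalizing substructure matcher
    that turns compound collections into per-molecule group-count profiles, and a
    two-set enrichment analyzer based on the exact hypergeometric test for
    structure-activity interpretation of labeled compound sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
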