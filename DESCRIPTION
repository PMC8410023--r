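Package: tcrdyn
Title: Dynamics of TCR-Beta Clonotype Repertoires After Hematopoietic Cell
    Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of T-cell receptor beta-chain
    CDR3 clonotype repertoires in hematopoietic-cell-transplant cohorts.
    Reads ImmunoSEQ- and AIRR-style rearrangement tables, normalizes samples
    to a common template depth by hypergeometric downsampling, computes
    diversity and clonal-expansion metrics (Inverse Simpson Index, richness,
    clonal space occupancy) with a reference-cohort-derived threshold for
    pathological expansion, quantifies donor-recipient clonotype sharing
    corrected for the public-clonotype background, annotates CDR3 sequences
    against specificity references, and computes Grantham-distance-based HLA
    evolutionary divergence. Ships a synthetic cohort generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
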