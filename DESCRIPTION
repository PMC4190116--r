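Package: pollenID
Title: DNA Barcoding Identification of Mixed Pollen Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Taxonomic identification of mixed pollen samples (honeybee pollen
    pellets) from clone libraries of the plastid barcodes rbcL and trnH-psbA.
    Provides a two-marker reference-database data model with pseudogene
    screening, a clone-library simulator with a substitution error model,
    semi-global pairwise alignment with BLAST-like percent identity, MOTU
    dereplication by single-linkage clustering with per-MOTU consensus,
    identity-threshold taxonomic assignment (99% rule) with genus-level
    collapse of ambiguous congeneric hits and two-marker reconciliation,
    site-by-sampling community composition summaries, and individual-based
    species-accumulation curves (randomized and analytic hypergeometric).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
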