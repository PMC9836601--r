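Package: mitoanchor
Title: Query-Anchored Mitogenome Reconstruction from Degraded Shotgun Reads
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs a circular mitochondrial genome from low-coverage,
    degraded (historical-DNA) shotgun libraries by anchoring reads on a related
    species' mitogenome: k-mer seeded banded local alignment with high/low
    stringency presets, a query-anchored pileup, per-site IUPAC ambiguity
    consensus calling with N for uncovered sites, quantification of cytosine
    deamination damage from the ambiguity spectrum, annotation liftover with
    per-feature recovery reports, query-independence validation, and a
    synthetic degraded-library simulator so every stage is testable against
    known truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
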