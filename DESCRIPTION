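Package: mcflfer
Title: Expanded Linear Free-Energy Relationship Models for Membrane-Coated
    Fiber Partition Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes membrane-coated fiber (MCF) partition coefficients from
    solid-phase microextraction quantities and models their base-10 logarithm
    with linear free-energy relationship (LFER) regressions on the Abraham
    solvation descriptors E, S, A, B and V. Implements the single LFER model,
    an expanded crossed-factors model with one coefficient block per treatment
    combination, and an expanded model that nests a log solute-concentration
    slope within each combination of metalworking fluid and fluid
    concentration. Provides replicate-aware leave-one-solute-out
    cross-validation (Q2-LOSO) alongside leave-one-out Q2, an extra
    sum-of-squares test battery for the partition theory that the coefficient
    is independent of the starting solute concentration, and a synthetic-data
    generator reproducing the 37-solute by 90-treatment-cell by 3-replicate
    study geometry for parameter-recovery and error-rate studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
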