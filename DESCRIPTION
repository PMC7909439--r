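Package: ufpept
Title: Predicting Peptide Yield, Enrichment and Purity in Batch Ultrafiltration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the yield, enrichment and purity of a target peptide
    (such as the antimicrobial pentapeptide neokyotorphin, 653 g/mol) in the
    permeate compartment of a batch tangential ultrafiltration, from a
    size-exclusion chromatogram of a protein hydrolysate and a membrane
    sieving calibration. Provides size-exclusion column calibration
    (elution time to log10 molar mass), per-residue absorbance-to-
    concentration conversion, pointwise membrane retention and its linear
    retention-versus-log10(MW) regression, apparent molecular-weight
    cut-off estimation, mass-balance prediction of permeate composition at
    any volume reduction factor, and a seeded synthetic-data generator with
    a brute-force batch simulation oracle so that every stage is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
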