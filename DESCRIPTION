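Package: anacardiq
Title: HPLC-DAD Quantification and Validation of Anacardic Acids in Cashew Peduncle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for external-standard quantification of anacardic
    acids (AnAc 15:3, 15:2, 15:1) in cashew peduncle by reversed-phase HPLC with
    diode-array detection. Covers chromatogram peak processing (baseline
    estimation, detection, trapezoidal integration, retention-time matching,
    three-point UV peak purity), calibration-line fitting with full
    coefficient-significance statistics (residual dispersion, slope and intercept
    standard deviations via the design determinant, Student's t and regression F
    tests), ICH-style validation parameters (intraday/interday precision, system
    suitability, LOD/LOQ, selectivity), and exhaustive sequential-extraction
    recovery with below-LOQ censoring, unit conversion to mg per 100 g dry
    weight, and per-clone totals. A synthetic-data generator produces DAD
    chromatograms, calibration series, and extraction depletion profiles with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
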