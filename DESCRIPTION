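Package: ntscreen
Title: Non-Targeted Compositional Screening of LC-HRMS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated non-targeted screening workflow for coupled liquid
    chromatography / ultrahigh-resolution mass spectrometry data from
    environmental matrices (ambient particulate matter, surface waters).
    Provides extracted-ion-chromatogram peak detection with signal-to-noise
    gating, molecular formula assignment with isotope-pattern verification,
    electrospray adduct grouping and blank subtraction, MS2 spectral library
    matching with identification-confidence levels, calibration-based
    quantification, and van Krevelen / DBE / carbon-oxidation-state
    compositional metrics and groupings. Includes a ground-truth-labelled
    synthetic data generator so every pipeline stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
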