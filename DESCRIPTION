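Package: peptiage
Title: Urinary Peptidome Ageing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for age-correlation analysis of urinary peptidome profiles
    measured by capillary electrophoresis coupled to mass spectrometry (CE-MS).
    Provides readers and writers for deconvoluted peak lists and cohort
    intensity matrices, calibration of mass and migration-time axes by locally
    weighted regression, intensity normalisation against internal-standard
    peptides, cross-sample peptide clustering with mass-ppm and migration-time
    tolerance windows, Spearman/Benjamini-Hochberg screening for age-correlated
    peptides, validation of peptide-sequence assignments from mass accuracy and
    predicted electrophoretic migration, cross-species (mouse/human) peptide
    orthology mapping by ungapped sequence overlap, and a support-vector-machine
    ageing score over a fixed peptide panel. A synthetic-cohort generator with
    programmed ground truth makes the full pipeline testable without access to
    raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
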