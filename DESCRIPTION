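Package: pillarscreen
Title: Purity-Gated Drug and Drug-Combination Screening on Micropillar Chips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis toolkit for immunofluorescence-based tumor-purity
    estimation and purity-gated drug screening of patient-derived cancer cell
    cultures on micropillar chips and 384-pillar plates. Computes the
    EpCAM/(EpCAM+vimentin) purity index with a linear calibration to true
    tumor fraction, fits four-parameter logistic dose-response curves with
    absolute IC50 extraction and censoring, scores two-drug combinations by
    the Loewe combination index (CI50) and Loewe/Bliss synergy-excess maps,
    filters variant tables and associates alteration status with synergy
    scores via permutation tests, and includes a seeded synthetic-data
    generator (co-culture mixture panels, rendered chip scans, dose-response
    matrices with known interaction ground truth) so the full pipeline is
    testable end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
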