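Package: glycoPRM
Title: Glycopeptide Fragment Annotation and PRM Fucosylation-Ratio Biomarker Evaluation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for site-specific N-glycopeptide analysis of stepped-HCD
    tandem mass spectra: theoretical monoisotopic masses for peptides, glycan
    compositions and their fragment ions (oxonium and glycosidic Y series),
    diagnostic-ion screening and core versus outer-arm fucosylation calls,
    glycoform profiling of identification tables, parallel reaction monitoring
    (PRM) Y1-ion chromatogram extraction and quantification with the
    fucosylation-ratio statistic, and cohort-level biomarker evaluation
    (two-sample power, t-tests, ROC/AUC, combination with serum AFP).
    Includes a synthetic-data generator for spectra, PRM runs and patient
    cohorts with known ground truth, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    mzR
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
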