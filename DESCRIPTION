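Package: fibrostep
Title: Stepwise Multi-Disciplinary Diagnosis of Fibrosing Lung Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying a stepwise, rule-based diagnostic algorithm for
    eight fibrosing lung diseases (UIP/IPF, fibrosing NSIP, chronic
    hypersensitivity pneumonitis, pleuroparenchymal fibroelastosis,
    post-tuberculous fibrosis, post-irradiation fibrosis, fibrosing
    sarcoidosis and progressive massive fibrosis), with a malignancy
    (scar carcinoma / metastasis) overlay driven by MRI and PET features.
    Provides a synthetic patient-cohort generator parameterised by published
    per-disease feature prevalences, one-vs-rest chi-square feature
    significance analysis, a deterministic ordered rule engine, and
    diagnostic-accuracy validation (sensitivity, specificity, PPV, NPV,
    accuracy, balanced accuracy) with exact Clopper-Pearson confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
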