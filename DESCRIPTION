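Package: mtapet
Title: Metabolic Tumour Area and PET-Based Prognostic Modelling for Lymphoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies FDG-PET tumour burden in lymphoma and models its
    prognostic value. Lesions are delineated by percentage-of-maximum
    thresholding (41% of the lesion peak SUV by default) with organ
    inclusion/exclusion rules, yielding total metabolic tumour volume
    (TMTV), the maximum axial cross-sectional area of the largest lesion
    (metabolic tumour area, MTA), SUVmax and SUVmean. Companion tools
    cover ROC analysis with Youden-index cut-off selection, Kaplan-Meier
    estimation, log-rank testing and Cox proportional-hazards regression
    implemented from first principles, NCCN-IPI risk scoring with
    MTA-based reclassification, and generators for digital PET phantoms
    and simulated survival cohorts used to validate the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC
Config/testthat/edition: 3
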