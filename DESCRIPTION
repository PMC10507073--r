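Package: ReadmitTA
Title: Multimodal Prediction of Unplanned ICU Readmission with Temporal
    Abstraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for predicting unplanned intensive-care-unit
    readmission from multimodal electronic health records. Implements
    cohort construction from MIMIC-III-schema tables (inclusion filters,
    30-day readmission labels, first-stay-per-year selection, patient-level
    stratified folds), knowledge-based temporal abstraction of vital signs
    and laboratory series (state discretization, gradient abstraction,
    temporal-linear interpolation), per-modality encodings (abstracted
    charts, ICD-9 code sequences and their textual descriptions,
    demographics, chunked discharge notes), a bidirectional GRU sequence
    classifier with attention and multimodal fusion, the AUPRC-driven
    training protocol with learning-rate decay and stop-loss early
    stopping, and multi-metric evaluation with chunk-score aggregation.
    Ships a seeded synthetic EHR generator emulating MIMIC-III structure
    with controllable per-modality signal, so the full pipeline is
    exercisable end to end without credentialed data access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    yaml,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
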