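Package: ehrfusion
Title: Multi-Modal Patient Representation Learning for Clinical Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns patient representations for binary clinical-outcome
    prediction (in-hospital mortality, 30-day readmission, long length of
    stay) by fusing three electronic-health-record modalities: static
    one-hot demographics and admission information, hourly-binned vital
    sign and laboratory time series from the first 24 hours of admission,
    and sequences of clinical-note document embeddings learned with
    PV-DBOW paragraph vectors. Provides two fusion architectures
    (convolutional and recurrent), logistic-regression and random-forest
    baselines on aggregated features, a synthetic multi-modal cohort
    generator with controllable cross-modal outcome signal, and an
    evaluation protocol with multi-run averages, t-distribution confidence
    intervals and pairwise t-test p-value matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    glmnet,
    ranger,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
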