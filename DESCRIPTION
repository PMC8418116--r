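Package: smartffr
Title: Virtual Functional Assessment of Coronary Stenoses from Vessel Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes SmartFFR, a geometry-derived functional index of coronary
    stenosis severity defined as the area under the patient-specific Pd/Pa
    versus flow curve over 0-4 ml/s divided by the healthy-vessel area (4).
    Includes a reduced-order pressure-drop engine (Poiseuille viscous loss plus
    a Young-Tsai separation loss), Murray's-law flow division for bifurcating
    trees, an adapter for externally computed pressure-flow samples, a
    synthetic-cohort generator pairing the index with a microvascular-resistance
    reference FFR, and the diagnostic-validation statistics used to assess such
    indices (confusion-matrix metrics, Pearson correlation, Bland-Altman
    agreement, ROC with Youden-optimal cutoff, and DeLong comparison of
    correlated ROC curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
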