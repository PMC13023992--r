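Package: tfrimsad
Title: Time-Frequency Respiratory Impedance Maps and Dual-Stream
    Classification of Small Airway Dysfunction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for within-breath analysis of impulse oscillometry (IOS)
    recordings. Converts raw oral pressure and airflow waveforms into
    coherence-screened time-frequency respiratory impedance maps (TFRIM),
    computes classical scalar IOS indices (R5, R20, R35, X5, Z5, Fres),
    and classifies spirometry-defined small airway dysfunction with a
    dual-stream network that couples a convolutional TFRIM encoder, a
    selective state-space (Mamba-style) temporal encoder, and
    demographics-driven affine feature modulation. A physics-based
    simulator with a time-varying resistance-inertance-compliance
    impedance model generates synthetic cohorts with known ground truth
    for end-to-end validation, and leakage-safe k-fold cross-validation
    with soft-label training mirrors the published evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
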