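Package: dyadnirs
Title: Dyadic Interaction Coding and Infant fNIRS Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying contingency in mother-infant interaction
    together with infant functional near-infrared spectroscopy (fNIRS)
    responses. Implements chance-corrected maternal responsiveness scoring
    from coded behavioral event streams, segment-based maternal touch
    aggregation, observer-reliability statistics (tolerance time-unit kappa,
    event-alignment kappa, Cohen's kappa, intraclass correlation), a complete
    fNIRS preprocessing chain from raw dual-wavelength intensity to
    baseline-corrected oxy-/deoxyhemoglobin region-of-interest epochs
    (channel pruning, optical density, motion-artifact detection and wavelet
    correction, heart-rate quality check, band-pass filtering, modified
    Beer-Lambert conversion), and the group-level statistics (time-bin
    repeated-measures ANOVA, condition difference scores, maternal-predictor
    regressions). A synthetic-data generator produces behavioral streams and
    block-design fNIRS recordings with known ground truth so the full
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
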