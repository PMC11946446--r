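Package: gazebci
Title: Hybrid SSVEP/EOG Brain-Computer Interface Cascade Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a hybrid brain-computer interface
    that combines a 7 Hz steady-state visual evoked potential (SSVEP) gate
    with four-class classification of eye-movement trajectories from
    electrooculographic (EOG) artifacts in frontal EEG channels. Provides a
    synthetic 14-channel EEG cohort generator emulating the study design
    (10 subjects, 800 recordings at 256 Hz), a preprocessing chain (beep
    trimming, 3 s segmentation, Butterworth band-pass filtering, z-scoring),
    a sliding-window Welch power spectral density estimator with a five-band,
    eight-statistic feature bank, the two-stage classification cascade
    (trapezoidal band-power-ratio LED gate, then trajectory classification
    with ANOVA feature ranking), and evaluation metrics including per-class
    accuracy, information transfer rate, channel ranking, and robustness
    reports.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    signal,
    pracma,
    e1071,
    randomForest,
    MASS,
    class,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
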