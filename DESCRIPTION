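Package: gammaflow
Title: Movement-Related Oscillation Features, TMS Inhibition Measures and
    Bayesian Correlation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis chain from movement-locked multichannel
    electrophysiology (MEG/EEG-like recordings with a surface EMG channel),
    transcranial magnetic stimulation (TMS) motor-evoked-potential trials,
    and motor-learning behavioural series to subject-level features and
    correlation inference. Provides continuous-data conditioning (polyphase
    resampling, zero-phase band-pass and notch filtering, generalised
    extreme studentised deviate bad-segment detection), EMG burst onset and
    offset detection, eigenvalue sensor normalisation and a linearly
    constrained minimum variance (LCMV) beamformer with PCA rank reduction,
    DPSS multitaper time-frequency decomposition with baseline correction
    and band-peak extraction (peak power, peak frequency, peak location),
    short-interval intracortical inhibition (SICI) ratios with rule-based
    trial rejection, motor-learning scores for a cued sequence task and a
    continuous tracing task, and default-prior Bayes-factor Pearson
    correlations with bootstrap Mahalanobis outlier removal and Fisher-z
    correlation comparisons. A synthetic-data generator with ground-truth
    labels makes every stage testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    MASS,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
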