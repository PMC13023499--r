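Package: edafaa
Title: Mutual Information Between Electrodermal Activity Features and Frontal Alpha Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Windowed feature extraction and information-theoretic analysis for
    multichannel psychophysiological recordings.  Decomposes electrodermal
    activity (EDA) into tonic and phasic components, detects skin conductance
    responses, computes complex-Morlet continuous-wavelet and variable-frequency
    complex-demodulation (TVSymp) features, heart-rate-variability RMSSD and
    three frontal-alpha-asymmetry (FAA) variants on a common moving-window grid;
    estimates mutual information between EDA features and FAA with
    equal-frequency binning, Miller-Madow bias correction and permutation
    significance; and derives emotional-state labels by hierarchical
    agglomerative clustering that feed a support-vector-machine classifier
    evaluated with leave-one-trial-out cross-validation.  A synthetic-session
    generator with a latent FAA trajectory and tunable FAA-to-tonic coupling
    makes the whole pipeline testable without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
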