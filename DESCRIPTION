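Package: mrcpbci
Title: Movement-Related Cortical Potential Detection for Brain-Computer
    Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, calibration, and real-time detection of
    movement-related cortical potentials (MRCP) from multi-channel EEG for
    brain-computer-interface neurofeedback applications. Provides a
    synthetic EEG generator with embedded MRCP templates and ground-truth
    peak-negativity latencies, the standard MRCP preprocessing chain
    (0.05-10 Hz band-pass, surface Laplacian, sensorimotor channel
    selection), four motor-intent detectors (rest-period thresholding,
    average peak-negativity timing, a multilayer perceptron, and a
    bidirectional LSTM sequence labeler), a deterministic tick-driven
    real-time trigger harness with true/false-positive and false-negative
    accounting, cross-session transfer learning with layer freezing, and
    the associated evaluation metrics (sample accuracy, detection-error
    statistics, event-related desynchronization, laterality index).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'mrcpbci-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'montage.R'
    'recording.R'
    'preprocess.R'
    'calibration.R'
    'simulate.R'
    'detectors.R'
    'evaluation.R'
    'transfer.R'
    'harness.R'
    'config.R'
    'readers.R'
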