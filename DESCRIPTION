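Package: reachDecode
Title: Hand-Trajectory Decoding with Linear, Kalman, and Hybrid
    Speed-Direction Filters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A benchmarking toolkit for decoding continuous 2-D hand
    trajectories from multichannel neural recordings such as MEG
    gradiometer signals. Implements three decoders: a lagged multiple
    linear regression filter, a standard velocity-state Kalman filter,
    and a hybrid Kalman filter that estimates hand speed and movement
    direction independently, reading speed out of a three-lag speed
    state through a multilayer perceptron trained by scaled conjugate
    gradients and direction out of a unit-normalized Kalman state.
    Includes the signal-conditioning chain (zero-phase band-pass
    filtering, downsampling, epoching, lagged design matrices,
    reach/rest labeling), trajectory evaluation metrics (position and
    speed RMSE plus the pointing-device measures ODC, MDC, ME and MV
    against the task axis), a seeded center-out reaching simulator with
    surrogate neural encoding, and a cross-validated benchmark pipeline
    comparing decoders under reach-only and reach-plus-rest regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'reachDecode-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'kinematics.R'
    'preprocessing.R'
    'linear-filter.R'
    'kalman.R'
    'mlp.R'
    'hybrid.R'
    'metrics.R'
    'synthetic.R'
    'pipeline.R'
    'io.R'
    'show-methods.R'
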