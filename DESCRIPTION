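Package: illusionflow
Title: Detecting Motion-Illusion-Like Signals in Static Images with a
    Predictive-Coding Video-Prediction Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for probing a hierarchical predictive-coding video-prediction
    network (a convolutional-LSTM hierarchy fed with prediction errors rather
    than raw frames) with static images, quantifying illusory-motion-like
    signals via sparse and dense optical flow between two successively
    predicted frames, summarising flow-magnitude distributions across image
    groups, constructing circular illusion-like test stimuli from image patches
    by tiling and polar warping, and analysing two-alternative rotation-nulling
    psychophysics with cumulative-Gaussian psychometric fits. Includes
    synthetic-data generators (training videos with coherent motion,
    illusion-style and control images, ground-truth flow fixtures, simulated
    observers) so the full pipeline runs end-to-end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    EBImage,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
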