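Package: hstarousal
Title: EEG-Free Sleep Arousal Detection from Limited-Channel Home Sleep
    Testing Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects cortical arousal events during sleep without an
    electroencephalogram, using combinations of signals that limited-channel
    home sleep testing devices can record: thoracic respiratory effort,
    ECG-derived heart rate, cannula snore vibration, body position, position
    change, and a hypnogram-derived wake/sleep indicator.  Provides a
    synthetic recording generator with ground-truth arousals and autonomic
    signatures, EDF and NSRR-style XML input/output, 4 Hz preprocessing with
    robust standardization and heart-rate outlier correction, a
    convolutional-recurrent sequence labeling network (inception block, two
    downsampling residual blocks, two LSTM layers) trained with truncated
    backpropagation through time, decision-threshold search with AASM-style
    event postprocessing (5 s merge, 3 s minimum duration), a three-level
    evaluation framework (pointwise, event-overlap, recordwise) with
    bootstrap paired testing, Holm correction, relative confusion matrices
    and Bland-Altman arousal-index agreement, and a greedy incremental
    signal-selection driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
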