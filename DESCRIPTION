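Package: hfpredict
Title: Hot-Flash Onset Prediction from Skin Conductance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting hot-flash (HF) event onsets from ambulatory
    skin-conductance (SC) recordings before they are subjectively perceived.
    Implements sliding-window feature extraction (median-subtracted integral
    and derivative features of a fitted biexponential curve), three-class
    cost-sensitive window labeling with distinct train and test schemes,
    univariate multinomial logistic models behind a robust scaling chain,
    event-level performance measures (prediction rate, identification rate,
    identification latency) alongside window-level confusion metrics, the
    classical 2 uS / 30 s threshold detector as a baseline, and a seeded
    synthetic SC session generator with ground-truth events for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
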