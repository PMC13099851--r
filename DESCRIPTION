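Package: gazeshiftr
Title: Gaze-Shift Detection for Head-Mounted Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects gaze shifts (saccades) in recordings from head-mounted
    eye trackers in dynamic, natural environments. Implements a rank-based
    probabilistic detector that converts eye velocity and acceleration into
    calibrated probabilities and optionally fuses them with scene-video
    patch-matching evidence, alongside three classical threshold-based
    baselines (I-DT, I-VT, and an adaptive moving-window method), a
    sample-level and majority-voting event-level F1 evaluation protocol,
    and a synthetic recording generator with exact ground truth for
    benchmarking without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
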