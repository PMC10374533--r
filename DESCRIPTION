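Package: pamscape
Title: Passive Acoustic Monitoring Pipeline for River-Dolphin Clicks, Boat
    Noise and Rain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end passive acoustic monitoring (PAM) workflow for
    freshwater soundscapes: reads and segments high-rate WAV recordings,
    builds 512 x 128 median-equalized log-Mel spectrogram images, trains a
    convolutional neural network that emits 16 per-class sigmoid scores per
    5-s segment, pools them with a 75th-percentile summary, evaluates with
    precision-recall / average-precision metrics, applies per-site decision
    thresholds with a posterior rain filter, and aggregates detections into
    daily acoustic presence, boat co-occurrence and day/night activity
    statistics. Includes a ground-truthed synthetic soundscape generator
    (dolphin echolocation click trains, boat engine noise, rain, insect
    background) so the whole pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
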