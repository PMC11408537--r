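Package: megstates
Title: Microstate Analysis for MEG and EEG Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identification and analysis of sensor-space microstates in
    magnetoencephalography (MEG) and electroencephalography (EEG)
    recordings. Implements modified k-means clustering of topographies at
    global field power peaks with a multi-index meta-criterion for
    selecting the number of microstates, competitive back-fitting with a
    spatial-correlation floor and Besag temporal smoothing, temporal
    metrics (coverage, duration, occurrence, global explained variance),
    segment-preserving permutation tests for parcel-level source
    activity and cross-modal co-occurrence, event-locked detection-rate
    and mismatch-negativity statistics, and a synthetic-data generator
    with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
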