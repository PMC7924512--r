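Package: ecgbeats
Title: Inter-Patient ECG Heartbeat Classification with Convolutional and
    RR-Interval Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies ECG heartbeats into the four AAMI arrhythmia classes
    (N, SVEB, VEB, F) under the inter-patient paradigm. Removes baseline wander
    with cascaded 200 ms / 600 ms median filters, cuts 200-sample segments
    around labeled R-peaks, extracts four RR-interval dynamic features, and
    trains a compact one-dimensional convolutional network whose flattened
    morphological features are concatenated with the RR features and fed to a
    multilayer perceptron. Training uses focal loss to counter the heavy class
    imbalance of ambulatory recordings. Includes a synthetic ECG generator, a
    minimal WFDB reader with the AAMI annotation mapping and the canonical
    DS1/DS2 record split for the MIT-BIH arrhythmia database, AAMI per-class
    evaluation metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
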