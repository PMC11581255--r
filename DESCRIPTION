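Package: mihawk
Title: Motor-Imagery EEG Classification with Wavelet-Packet Preprocessing
    and Harris-Hawks Hyperparameter Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying motor-imagery (MI)
    electroencephalography (EEG) epochs in brain-computer interface (BCI)
    settings. Epochs are band-limited by wavelet packet decomposition (WPD),
    passed through a densely connected convolutional feature extractor with
    squeeze-and-excitation (SE) channel recalibration, and classified by a
    convolutional autoencoder (CAE) with a softmax head. Classifier
    hyperparameters (learning rate, batch size, network depth) are tuned by a
    boosted Harris Hawks optimizer hybridised with a shuffled-shepherd
    position update and Levy-flight dives. A seeded synthetic MI-EEG
    generator with contralateral mu/beta event-related desynchronization
    (ERD) over 1/f background noise makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
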