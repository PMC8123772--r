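Package: topospectra
Title: Topographic Spectral Images from Multichannel EEG and a
    Convolutional Classification Harness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds 2-D and 3-D topographic spectral images from
    32-channel EEG recordings and classifies emotional states of calm and
    distress with an AlexNet-shaped convolutional network. Covers the full
    chain: valence/arousal trial labeling, preprocessing (polyphase
    downsampling, average re-referencing, zero-phase band-pass filtering,
    epoching), Welch band-power estimation with normalized theta, alpha,
    beta and gamma fractions, three electrode-to-image mapping schemes
    (direct 9x4 matrix distribution, its biharmonic-spline interpolated
    variant, and azimuthal equidistant projection), jet colormap rendering,
    227x227x5 spectral cubes, and a hold-out experiment protocol reporting
    sensitivity, specificity and accuracy. A synthetic EEG generator with
    controlled band-power structure makes every stage testable without
    access to restricted recordings.
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
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
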