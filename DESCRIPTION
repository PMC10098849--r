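Package: bcgsleep
Title: Sleep Apnea Screening from Bed-Pressure Ballistocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for single-channel bed-pressure recordings:
    separates ballistocardiogram (BCG) and respiration by Daubechies-5
    wavelet band reconstruction with soft-threshold denoising, detects and
    corrects J-peaks, segments breath frames and extracts per-frame heart
    rate variability and waveform-similarity features, and classifies
    frames as apnea or normal with a binomial logistic regression fitted
    by maximum likelihood. Includes a synthetic bed-signal generator with
    ground-truth annotations, and Pearson/Bland-Altman agreement analysis
    for validating derived measurements against a reference.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
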