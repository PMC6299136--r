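Package: remsurge
Title: Sleep-State Hemodynamics and Neurovascular Coupling from Concurrent
    Functional Ultrasound and Hippocampal LFP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for concurrent functional-ultrasound (fUS)
    power-Doppler imaging and hippocampal local field potential (LFP)
    recordings during natural sleep in rodents. Provides sleep-state scoring
    from EMG, accelerometer and LFP; SVD clutter filtering of ultrafast
    Doppler frame stacks; cerebral-blood-volume (CBV) normalization against a
    quiet-wake baseline; detection of brain-wide vascular surges during REM
    sleep by a population activity threshold; band-limited LFP power
    envelopes, frequency-compensated wavelet spectrograms and theta-gamma
    phase-amplitude coupling; LFP-CBV peak pairing, delay statistics and
    per-episode cross-correlation lag estimation; state-wise functional
    connectivity with Fisher confidence intervals; landmark-based
    registration of a 2-D imaging plane into a 3-D label volume; and a
    seeded multimodal synthetic-recording generator with full ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    rlang,
    EBImage,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
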