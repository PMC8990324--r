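Package: valenceloop
Title: Closed-Loop Tracking and Fuzzy Regulation of a Latent Emotional
    Valence State from Facial EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to track and regulate a latent emotional valence state
    from facial electromyography (zygomaticus major, zEMG). The package
    extracts binary spike-like and continuous log-bandpower features from
    raw EMG, estimates the hidden valence state and its person-specific
    state-space parameters with a mixed Bernoulli/Gaussian Kalman filter,
    fixed-interval smoother and expectation-maximization, models
    environmental stimuli as a high-order sinusoidal harmonic process, and
    closes the loop around a simulated virtual subject with a Mamdani fuzzy
    controller in inhibitory or excitatory mode. Includes a synthetic zEMG
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
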