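Package: rhythmnet
Title: Rhythmic Attention Analysis for Pulvino-Cortical Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for multi-region spike and local field potential
    (LFP) recordings collected during covert spatial attention tasks:
    Gaussian-kernel spike rates and randomization tests of task
    responsiveness, Morlet and Hanning-taper spectral estimation with
    IRASA fractal/oscillatory separation, phase-detection functions
    linking pre-target oscillatory phase to behavioral hit rate,
    spike-LFP pairwise phase consistency (PPC) with power-equating
    stratification controls, parametric (MVAR) spectral and conditional
    Granger causality including theta-phase-binned variants, and
    phase-amplitude coupling (PAC) within and between regions.  A
    synthetic-session generator reproduces the statistical structure
    these analyses assume (1/f background, theta-nested alpha/low-beta
    bursts, phase-coupled spiking, directed vector-autoregressive
    influence, phase-dependent detection), so every estimator is
    verifiable by parameter recovery.
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
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
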