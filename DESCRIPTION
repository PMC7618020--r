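Package: MEGmarkers
Title: Lempel-Ziv Complexity and Theta-Alpha Ratio Markers for Resting-State MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes two sensor-level neurophysiological markers from epoched
    resting-state magnetoencephalography (MEG) recordings: normalized
    Lempel-Ziv (LZ76) complexity averaged over random gradiometer subsets
    ("LZsum", a proxy for signal diversity and conscious level) and the
    theta-alpha band-power ratio (TAR, a proxy for arousal/drowsiness).
    Includes a preprocessing chain (resampling, zero-phase filtering,
    epoching, automated muscle-artifact rejection), a synthetic multichannel
    cohort generator with controllable spectral content, temporal
    predictability and cognitive-score coupling, a covariate-adjusted
    group-comparison and regression battery, and a reproducible end-to-end
    pipeline with documented on-disk formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
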