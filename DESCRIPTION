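Package: sparkfmri
Title: Desk-Scale Comparison of Non-Cartesian SPARKLING and Cartesian EPI
    Encoding for Retinotopic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to design variable-density non-Cartesian k-space sampling
    patterns by constrained attraction-repulsion optimization, to simulate
    multi-coil off-resonance-affected fMRI acquisitions on a synthetic
    retinotopic phantom, to reconstruct image series by l1-wavelet compressed
    sensing (POGM) or linear least squares, to fit a two-session prewhitened
    general linear model with effect-of-interest F tests and retinotopic
    phase maps, and to score the results with a battery of quality metrics
    (temporal SNR, Dice overlap, tissue specificity, Kolmogorov-Smirnov
    shift tests, residual normality).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
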