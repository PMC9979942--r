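Package: stillgauss
Title: Gaussian Modelling of Still-Crystal Diffraction, Partiality and Merging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form Gaussian-basis modelling of serial snapshot
    crystallography. Models the illumination (bandwidth, divergence,
    polarization), the crystal (reciprocal cell, peak shape, mosaicity,
    strain) and the detector (rigid panels) as three-dimensional Gaussian
    kernels, and combines them analytically to predict diffraction
    patterns pixel by pixel, integrated reflection intensities and
    partialities of still patterns. A maximum-likelihood merging engine
    (Gaussian plus Cauchy outlier mixture) jointly estimates per-crystal
    scaling and disorder parameters together with merged structure-factor
    intensities, and a synthetic-data generator reproduces the assumed
    statistical structure of an indexed-stills data set for end-to-end
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
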