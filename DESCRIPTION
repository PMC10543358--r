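Package: linetarget
Title: Selection and Targeting of Cortical Locations for Line-Scanning fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for planning and validating line-scanning functional MRI
    acquisitions. Selects a target vertex on a cortical surface mesh from
    population receptive field (pRF) and curvature criteria, converts it to a
    scanner-frame line placement (translation, angulation, slice orientation,
    nominal line mask), processes multi-coil multi-echo line time series
    through an SVD-denoising, coil/echo-combination, drift-removal, aCompCor
    and smoothing chain, fits Gaussian pRF models, and quantifies targeting
    accuracy with anatomical (registration dispersion, curvature, tissue
    fractions) and functional (cross-validated variance explained,
    best-matching-vertex distance) metrics. Includes seeded synthetic
    generators of every input (folded cortical sheet, retinotopic maps,
    simulated line sessions) so the full pipeline can be exercised end to end
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    igraph,
    signal,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
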