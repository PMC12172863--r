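Package: sefmapper
Title: Delineation of Somatosensory Cortex from MEG Evoked Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for delineating the primary somatosensory cortex from
    magnetoencephalography (MEG) somatosensory evoked fields. Implements a
    distributed-source post-processing pipeline: sLORETA inverse imaging on a
    cortical source space, anatomy-aware spatial filtering, windowed singular
    value decomposition of the source time courses, and thresholding of the
    dominant spatial mode into an activation region with a defined boundary.
    Includes an analytic spherical-conductor MEG forward model for a
    306-channel array (102 magnetometers, 204 planar gradiometers), a
    synthetic two-hemisphere cortical workbench with a band parcellation and
    ground-truth activation patches, equivalent current dipole fitting with
    goodness of fit, and a statistical evaluation suite (atlas overlap,
    sphere overlap, centroid distances, size-matched random-patch permutation
    nulls, binomial, Wilcoxon signed-rank and chi-squared cohort tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
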