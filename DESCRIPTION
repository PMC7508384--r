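Package: vesselmorph
Title: Morphogenesis Analysis of Wheel-Thrown Vessel Outlines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the staged development of axisymmetric vessel
    shapes from digitized cross-sectional profiles. Profiles are
    calibrated, resampled and smoothed, mirrored into closed outlines,
    and decomposed with elliptical Fourier analysis; size-normalized
    coefficients span a PCA shape space in which per-trial morphogenetic
    trajectories are traced. Among- versus within-individual shape
    variation is tested with distance-based permutation tests, size
    growth is modelled with orthogonal-polynomial mixed-effects growth
    curves, and convergence toward a common final form is tested with a
    heteroscedastic linear mixed model on shape-space distances. A
    synthetic-data module generates staged vessel profiles with
    individual-specific morphogenesis routes for validation and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    lme4,
    nlme
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
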