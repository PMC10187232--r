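Package: spindlemetrics
Title: Quantitative Analysis of Mitotic Spindle Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for quantifying mitotic-spindle phenotypes
    from multi-channel fluorescence microscopy: chromosome alignment as the
    full width at half maximum (FWHM) of a Gaussian fitted to the kinetochore
    intensity profile along the pole-to-pole axis, spindle length and
    inter-pole focal-plane angle, spindle rotation from pole tracks,
    peripheral-versus-spindle intensity ratios from morphological band ROIs
    and quartile line scans, single-molecule velocities from kymographs, and
    mitotic timing and arrest tabulation, with one-way ANOVA/Tukey and
    Kruskal-Wallis/Dunn group comparisons. Includes a synthetic-microscopy
    generator producing bipolar and monopolar spindle images, rotating-spindle
    time lapses and kymographs with full ground-truth manifests, used for
    recovery testing of every measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
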