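Package: cardiopiv
Title: Multigrid Ensemble Micro-PIV and Hemodynamic Quantitation for
    Beating-Heart Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify intracardiac hemodynamics from time-lapse
    movies of tracer particles (for example fluorescently labeled red blood
    cells) in the beating zebrafish heart.  Implements cardiac-cycle phase
    alignment by whole-image temporal cross-correlation, multigrid ensemble
    particle image velocimetry with correlation-plane averaging over
    same-phase frame pairs, cross-sectional flow-rate integration,
    phase-resolved flow profiles and the Fundamental Harmonic Index
    (the ratio of the fundamental flow harmonic to mean flow, a measure of
    oscillatory versus unidirectional flow).  Also provides the standard
    image-quantitation formulas used alongside such recordings (fractional
    area change, background-corrected mean fluorescence, labeled-area
    coverage, normalized chamber area) and a synthetic movie generator with
    analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
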