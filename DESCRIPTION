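Package: cowhemo
Title: Reduced-Order Hemodynamics and Group Statistics for the Mouse Circle of Willis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying angioarchitectonics and hemodynamics of the
    mouse circle of Willis in experimental type-1 diabetes. Provides a vascular
    network data model with bifurcation angles and cross-section planes, a
    steady lumped Poiseuille-conductance blood-flow solver with
    area-proportional outlet boundary conditions, a pulsatile counterpart built
    on rigid-tube Womersley impedances with harmonic decomposition of the
    inlet waveform, formula-defined hemodynamic metrics (sectional mass flow,
    maximum velocity, pairwise hydraulic resistance), a synthetic cohort
    generator calibrated to published group statistics of control and diabetic
    animals, and a statistics pipeline with Kolmogorov-Smirnov normality
    screening, two-group t-tests, left/right asymmetry tests, NIPALS PLS-DA
    with stepwise variable elimination, and two-way ANOVA on discriminant
    scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
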