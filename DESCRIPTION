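Package: vmatmetrics
Title: Plan Quality and MLC Complexity Metrics for Dual-Arc VMAT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dose-volumetric and multi-leaf-collimator (MLC) aperture
    complexity analysis for volumetric-modulated arc therapy (VMAT)
    treatment plans. Computes cumulative dose-volume histograms and the
    derived indices (D_x%, D_0.03cc, D_mean, conformity number,
    homogeneity index, gradient index), the MU-weighted modulation
    complexity score MCSv with its leaf-sequence and aperture-area
    variability components, and the aperture-geometry family (aperture
    area, perimeter, irregularity; beam- and plan-averaged area,
    irregularity and modulation). Reads plans from DICOM-RT Plan files
    or a documented JSON dialect, aggregates paired cohorts with exact
    Wilcoxon signed-rank tests, and ships a seeded synthetic-cohort
    generator emulating dual-arc head-and-neck plans (arc-increment
    groups 30/30, 15/15, 30/15) so the whole pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
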