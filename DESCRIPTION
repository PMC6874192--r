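Package: protoscatter
Title: Patient and Compensator Scatter Factors for Passive-Scattering
    Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study the patient scatter factor (PSF) and compensator
    scatter factor (CSF) that correct the dose-per-monitor-unit calibration of
    passive-scattering proton therapy fields. Provides a simplified analytic
    pencil-beam dose engine (Bragg-Kleeman range, spread-out Bragg peak
    construction, Highland multiple-Coulomb-scattering widths, exact
    voxel-boundary water-equivalent-depth ray tracing), synthetic voxel
    phantom generators with controllable air and dense-bone content,
    Hounsfield-unit material classification and stopping-power calibration,
    range-compensator design with the interquartile-range irregularity metric,
    the water-phantom verification workflow that defines PSF and CSF, field
    material-composition analysis, empirical linear predictors, and packaged
    study tables with their agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
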