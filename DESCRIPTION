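Package: ctspr
Title: CT-Number to Material Assignment for Carbon-Ion Radiotherapy Dose
    Reconstruction
Version: 0.1.0
Authors@R: person("ctspr", "developers", role = c("aut", "cre"),
    email = "ctspr@example.org")
Description: Converts CT numbers (Hounsfield units) to Monte Carlo material
    definitions for carbon-ion radiotherapy dose reconstruction.  Reference
    human-tissue elemental compositions are assigned by HU interval and the
    mass density of each 10-HU bin is solved from a treatment-planning-system
    HU-SPR calibration curve through a Bethe-Bloch stopping-power ratio with
    Bragg-additivity mean excitation energies.  Companion tools cover the
    varying-density-water comparison method, dose-to-water conversion,
    geometric nucleus-nucleus reaction cross-sections and the
    nuclear-interaction probability ratio, 1-D layered phantoms with
    water-equivalent-path-length range scaling of a spread-out Bragg peak,
    range-difference metrics and a 1-D gamma-index analysis, plus a command
    line interface and PHITS-style material-card export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
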