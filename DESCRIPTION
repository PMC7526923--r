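Package: batradar
Title: Spatial Detection Volume Modelling for Marine Radar Monitoring of Bats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical spatial detection volume model for onshore monitoring
    of bat-sized objects with an X-band marine pulse radar. Implements the
    radar-equation link budget and its calibration against a conducting
    reference sphere (Mie-series radar cross section), water-sphere RCS
    models for small animals, Fresnel knife-edge diffraction of a clutter
    shielding fence, two-dimensional received-power fields with detection
    boundaries, clutter-threshold visibility analysis of quantized PPI radar
    images including the multi-frame echo visibility procedure, and the
    integration of both into a 3D detection volume with fence-height and
    clutter-threshold optimization sweeps. Includes a seeded synthetic PPI
    scene generator so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
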