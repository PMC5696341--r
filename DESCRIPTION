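Package: endoflow
Title: Quantification of Endothelial Responses to Fluid Shear Stress
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify endothelial cell responses to fluid flow from
    live-cell fluorescence imaging and phase-contrast velocimetry. The package
    segments calcium-indicator movies into per-cell traces, removes slow
    photobleaching with an asymmetric-loss nonlinear fit, converts fluorescence
    to calcium concentration with a single-wavelength indicator calibration
    (per-cell Fmin/Fmax and the indicator dissociation constant), detects and
    summarizes calcium spikes, and compares conditions nonparametrically. It
    also measures monolayer morphometry (elongation, orientation, junction
    coverage, organelle polarity, protein-polarization kinetics) relative to
    the flow axis, and converts gridded velocity fields into wall shear stress
    maps under a parallel-plate assumption. A fully seeded synthetic-data
    generator produces every input with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
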