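Package: leadrecon
Title: Universal 12-Lead ECG Reconstruction from Chest-Patch Electrode Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates cohorts of multichannel chest-grid electrocardiogram
    recordings with a dipole volume-conductor forward model, derives bipolar
    chest leads from four-electrode combinations on a 7 x 5 grid, fits
    universal (subject-pooled) multiple linear regression and single-hidden-
    layer feedforward neural network transformations from three chest leads
    to the standard 12-lead ECG, and ranks electrode combinations and patch
    shapes by mean and minimum per-lead correlation, including a positional
    robustness analysis under one-step electrode misplacement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
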