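Package: paracest
Title: Dual-Agent paraCEST MRI Simulation and Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification toolkit for dual-agent
    paraCEST (paramagnetic chemical exchange saturation transfer) MRI
    cell-tracking studies. Implements multi-pool Bloch-McConnell
    forward simulation of z-spectra under continuous rectangular
    saturation, including a super-Lorentzian semisolid magnetization
    transfer pool; Hanes-Woolf linear QUESP exchange-rate estimation;
    z-spectrum normalization, spline smoothing, MTR asymmetry and
    banded AUC contrast with linear concentration calibration and
    detection-threshold inversion; WASSR B0 field mapping by the
    maximum-symmetry algorithm with voxelwise z-spectrum recentring;
    dual-channel (Eu-HPDO3A at 18 ppm / Yb-HPDO3A at 97 ppm) contrast
    mapping with ROI statistics and overlays; and a deterministic
    synthetic-phantom generator for tube grids and lesion-slice
    dual-label cell implants with tissue MT, B0 inhomogeneity and
    acquisition noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
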