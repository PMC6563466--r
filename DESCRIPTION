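Package: cestb0
Title: Static and Dynamic B0 Field-Map Correction for CEST MRI Z-Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping and correcting static-field (B0) inhomogeneity
    and temporal frequency drift in chemical exchange saturation transfer
    (CEST) MRI. Implements three static water-frequency referencing methods
    (Z-spectrum minimum after smoothing-spline interpolation, WASSR Lorentzian
    fitting of a low-power prescan, and dual-echo gradient-echo phase mapping
    with Hermitian-inner-product multi-coil combination) and three dynamic
    per-offset methods (intrinsic dual-echo and single-echo CEST readout phase
    mapping, and an interleaved dual-echo navigator), together with Z-spectrum
    resampling correction, MTR-asymmetry quantification, a two-pool
    Bloch-McConnell saturation simulator with multi-coil complex image
    synthesis, NIfTI/JSON dataset input and output, and an in-silico
    scan-rescan drift experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    mgcv,
    minpack.lm,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
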