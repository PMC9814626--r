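Package: shgmap
Title: Membrane Potential, Charge and Curvature Maps from Second-Harmonic Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for wide-field second-harmonic (SH) images of
    freestanding lipid bilayers. Converts photon-count image stacks into maps of
    trans-membrane potential (via external-bias calibration of the quadratic
    SH response), surface charge density (parallel-plate capacitor model),
    ion-lipid binding free energy and dissociation constant, flexoelectric
    curvature and membrane topography. Includes spatial and temporal image
    autocorrelation analysis (SACF/TACF with Gaussian fits) to size transient
    ordered-water domains and bound their lifetime, and a synthetic SH image
    generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
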