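Package: y90dose
Title: Voxel Dosimetry and Activity Planning for Intra-Arterial Y-90
    Microbubble Brain Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based voxel dosimetry for intra-arterial infusion of
    yttrium-90 labelled microbubble carriers in the brain.  Generates a Y-90
    dose voxel kernel by Monte Carlo transport of the beta spectrum in
    water-equivalent medium (with an attenuated point-kernel bremsstrahlung
    tail), maps contrast-enhanced MRI intensity to a voxel activity
    distribution, convolves cumulated activity with the kernel to obtain
    absorbed dose, computes biologically effective dose under the
    linear-quadratic model for both the permanent-implant radionuclide regime
    and a fractionated external-beam comparator, and solves for administered
    activities that reach dose-coverage (A95/A99) or BED-matching
    prescriptions.  Includes a seeded synthetic brain/tumor phantom generator
    and a parametric external-beam surrogate so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
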