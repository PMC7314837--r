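Package: islandmech
Title: Force and Motion in Confined Collective Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures force and motion in micropatterned cell islands from
    time-lapse microscopy. Subset-based digital image correlation turns
    consecutive phase-contrast frames into cell velocity fields and
    particle/reference image pairs into substrate displacement fields;
    Fourier-transform traction microscopy inverts substrate displacements to
    cell-substrate tractions on an elastic half-space; monolayer stress
    microscopy recovers the in-plane stress tensor of the cell sheet by a
    plane-stress finite-element solve of the force balance closed with a
    compatibility constraint. A forward-model generator produces
    ground-truthed synthetic islands (velocity field to strain rate to
    stress to traction to substrate displacement to speckle images) so that
    every inverse stage can be verified without experimental data, and
    technical-validation metrics (traction localization ratio,
    edge-traction direction, contractile tension normalization) are
    provided as reusable checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
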