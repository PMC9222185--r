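Package: polartrack
Title: Brainstem-Tracking Polar U-Net for Posterior Circulation Thrombus
    Localization and Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Localizes and segments occluding thrombi of the posterior
    cerebral circulation (vertebral, basilar and posterior cerebral
    arteries) on 3D CT volumes. Implements a moving volume-of-interest
    tracker steered by regressed polar coordinates and a discrete action
    head on top of a 3D residual U-Net (Polar-UNet), a grid-based baseline
    U-Net, volume-based removal of small false-positive components, and
    the full localization and volumetry evaluation protocol (connected
    component matching with an overlap criterion, Dice, intra-class
    correlation, Bland-Altman limits of agreement, paired testing with
    Bonferroni correction). Ships a synthetic head-phantom generator with
    reference path and thrombus annotations so the whole pipeline runs
    end-to-end without clinical data, plus NIfTI and MetaImage volume IO
    and the standard Hounsfield-unit preprocessing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
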