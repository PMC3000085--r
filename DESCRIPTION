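Package: qsar3d
Title: Grid-Based 3D-QSAR with CoMFA/CoMSIA Fields and PLS Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds comparative molecular field analysis (CoMFA) and
    comparative molecular similarity indices analysis (CoMSIA) descriptors
    on a cubic lattice for rigidly aligned congeneric small-molecule
    series, fits partial-least-squares (PLS) activity models with the full
    classical validation battery (leave-one-out q2, SEP, non-cross-validated
    r2, SEE, F, bootstrap, predictive r2 on an external test set), searches
    all field-kind combinations for the best model, flags residual
    outliers, and extracts StDev*Coeff contour grids with favored and
    disfavored isolevels exported as OpenDX or Gaussian cube volumes.
    Includes a synthetic congeneric-series generator with planted
    field-activity structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    ChemmineR,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
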