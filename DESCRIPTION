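Package: epimech
Title: Biomechanics of the Growing Epiphysis: Plane-Strain Finite Elements,
    Indentation and Allometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the secondary ossification center
    mechanically shields growth-plate chondrocytes. Implements a parametric
    plane-strain finite-element model of the cartilaginous epiphysis with
    swappable stiff subdomains (ossification center or ossified protrusions),
    a total-Lagrangian Saint Venant-Kirchhoff solver with follower sector
    pressure loads, second Piola-Kirchhoff stress post-processing (hydrostatic,
    lowest principal and octahedral shear measures), ex-vivo mechanical-test
    property extraction (stiffness, oval-area stress, 0.2 percent offset
    yield), Hertzian indentation fitting for AFM and nanoindenter force
    curves, and allometric pressure-scaling calculations, together with
    synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
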