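Package: coxafem
Title: Parametric Finite-Element Analysis of Femoral Head Necrosis Under Hip Abduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale parametric biomechanics pipeline for pre-collapse
    osteonecrosis of the femoral head. Generates a two-dimensional coronal-plane
    proximal femur with cortical shell, trabecular interior and a JIC-classified
    necrotic wedge; builds a conforming triangular mesh; applies single-leg-stance
    joint contact pressure (rotated by the hip abduction angle) together with seven
    muscle point loads; solves plane-strain linear elasticity with constant-strain
    triangles; and evaluates the principal-compressive-stress field, the
    load-share ratio S1/S2 between the subchondral cortical column and the
    trabecular stress-transfer corridor, active load-carrying area, and a
    lesion-severity classifier across the full 5 condition x 6 abduction-angle
    model grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
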