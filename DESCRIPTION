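Package: airpuffr
Title: Inverse Finite-Element Reconstruction of Corneal Hyperelastic
    Properties from Air-Puff Deformation Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs inherent Mooney-Rivlin hyperelastic material
    parameters (C10, C01) of corneas and hydrogel corneal phantoms from
    air-puff deformation imaging of the Corvis ST type. Provides an
    axisymmetric total-Lagrangian nonlinear finite-element solver with
    follower pressure loads and selective reduced integration for
    near-incompressibility, a parameterized air-pulse load model, the
    standard deformation metrics (deformation amplitude, peripheral
    deformation amplitude, central-peripheral ratio, time to highest
    concavity), an inverse-identification loop combining an ordinary
    Kriging surrogate with a genetic algorithm, a uniaxial tensile-test
    simulator for cross-validation via the equivalent Young's modulus,
    and a seeded synthetic-measurement generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
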