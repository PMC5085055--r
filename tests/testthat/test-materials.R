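test_that("strain energy vanishes at the undeformed state and under rotation", {
  mat <- mooney_rivlin(0.3, 0.1)
  expect_identical(strain_energy(deformation_state(diag(3)), mat), 0)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_lt(abs(strain_energy(deformation_state(R), mat)), 1e-14)
})

test_that("strain energy matches the hand-evaluated isochoric uniaxial value", {
  lam <- 1.5
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  W <- strain_energy(deformation_state(F), mooney_rivlin(0.3, 0.1))
  I1 <- lam^2 + 2 / lam
  I2 <- 2 * lam + 1 / lam^2
  expect_equal(W, 0.3 * (I1 - 3) + 0.1 * (I2 - 3), tolerance = 1e-12)
  expect_equal(W, 0.2194444, tolerance = 1e-6)
})

test_that("energy is objective and non-negative over random states", {
  set.seed(11)
  mat <- mooney_rivlin(0.2, 0.05)
  for (i in 1:50) {
    F <- random_axisym_F()
    if (det(F) <= 0) next
    W <- strain_energy(deformation_state(F), mat)
    expect_gte(W, -1e-14)
    # objectivity: energy invariant under appended rotation
    th <- stats::runif(1, 0, 2 * pi)
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    W_rot <- strain_energy(deformation_state(R %*% F), mat)
    expect_equal(W_rot, W, tolerance = 1e-10)
  }
})

test_that("invalid deformation states are rejected", {
  expect_error(deformation_state(diag(c(-1, 1, 1))), "det")
  expect_error(mooney_rivlin(-0.3, 0.1), "positive")
  expect_error(mooney_rivlin(0.3, 0.1, bulk_penalty = 1), "100")
})

test_that("constitutive update gives zero stress at identity and the analytic shear modulus", {
  mat <- mooney_rivlin(0.3, 0.1)
  cu <- constitutive_update(deformation_state(diag(3)), mat)
  expect_lt(max(abs(cu$cauchy)), 1e-14)
  expect_lt(max(abs(cu$S)), 1e-14)
  # small-strain shear modulus extracted from the tangent
  expect_equal(cu$tangent[4, 4], 2 * (0.3 + 0.1), tolerance = 1e-12)
  expect_equal(cu$tangent, t(cu$tangent))
})

test_that("material tangent equals finite differences of the stress", {
  set.seed(21)
  mat <- mooney_rivlin(0.3, 0.1)
  h <- 1e-6
  svoigt <- function(C) {
    # any F with F'F = C gives the same PK2 stress; chol supplies one
    F <- chol(C)
    S <- constitutive_update(deformation_state(F), mat)$S
    c(S[1, 1], S[2, 2], S[3, 3], S[1, 2])
  }
  for (i in 1:20) {
    F0 <- random_axisym_F()
    if (det(F0) <= 0.3) next
    C0 <- t(F0) %*% F0
    D <- constitutive_update(deformation_state(F0), mat)$tangent
    # columns of D are dS/de with e = (E11, E22, E33, gamma); E = (C - I)/2
    Dfd <- matrix(0, 4, 4)
    for (k in 1:3) {
      Cp <- C0; Cp[k, k] <- Cp[k, k] + h
      Cm <- C0; Cm[k, k] <- Cm[k, k] - h
      Dfd[, k] <- (svoigt(Cp) - svoigt(Cm)) / (2 * h) * 2 # dC_kk = 2 dE_kk
    }
    Cp <- C0; Cp[1, 2] <- Cp[1, 2] + h; Cp[2, 1] <- Cp[2, 1] + h
    Cm <- C0; Cm[1, 2] <- Cm[1, 2] - h; Cm[2, 1] <- Cm[2, 1] - h
    Dfd[, 4] <- (svoigt(Cp) - svoigt(Cm)) / (2 * h) # dC_12 = d gamma
    expect_lt(max(abs(Dfd - D)) / max(abs(D)), 1e-4)
  }
})

test_that("uniaxial nominal stress matches the closed form and is monotone", {
  mat <- mooney_rivlin(0.3, 0.1)
  expect_identical(uniaxial_nominal_stress(1, mat), 0)
  expect_equal(uniaxial_nominal_stress(1.5, mat),
               2 * (1.5 - 1.5^-2) * (0.3 + 0.1 / 1.5), tolerance = 1e-12)
  expect_equal(uniaxial_nominal_stress(1.5, mat), 0.7740741, tolerance = 1e-6)
  # initial slope is the analytic small-strain Young's modulus
  h <- 1e-7
  slope <- (uniaxial_nominal_stress(1 + h, mat) -
            uniaxial_nominal_stress(1 - h, mat)) / (2 * h)
  expect_equal(slope, 6 * (0.3 + 0.1), tolerance = 1e-6)
  lam <- seq(1, 2, length.out = 101)
  expect_true(all(diff(uniaxial_nominal_stress(lam, mat)) > 0))
})
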