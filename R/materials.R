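#' Mooney-Rivlin material parameters
#'
#' Constructs the two-parameter incompressible Mooney-Rivlin material used for
#' the cornea, \eqn{W = C_{10}(\bar I_1 - 3) + C_{01}(\bar I_2 - 3) +
#' \kappa/2\,(J-1)^2}, where \eqn{\bar I_1, \bar I_2} are the isochoric
#' invariants of the left Cauchy-Green tensor and \eqn{\kappa} is a volumetric
#' penalty enforcing near-incompressibility in a pure-displacement finite
#' element setting.
#'
#' @param c10,c01 Material constants in MPa. The small-strain shear modulus is
#'   \eqn{\mu = 2(C_{10}+C_{01})} and must be positive.
#' @param bulk_penalty Volumetric penalty stiffness in MPa. Defaults to
#'   \eqn{1000\mu}; must be at least \eqn{100\mu} to stay in the
#'   near-incompressible regime.
#' @return An object of class `mooney_rivlin` with fields `c10`, `c01`,
#'   `bulk_penalty`.
#' @examples
#' mat <- mooney_rivlin(0.0375, 0.0125) # equivalent modulus 6*(c10+c01) = 0.3
#' @export
mooney_rivlin <- function(c10, c01, bulk_penalty = NULL) {
  stopifnot(is.numeric(c10), is.numeric(c01), length(c10) == 1L, length(c01) == 1L)
  mu <- 2 * (c10 + c01)
  if (!is.finite(mu) || mu <= 0) {
    stop("shear modulus 2*(c10 + c01) must be positive", call. = FALSE)
  }
  if (is.null(bulk_penalty)) bulk_penalty <- 1000 * mu
  if (bulk_penalty < 100 * mu) {
    stop("bulk_penalty must be >= 100 * shear modulus (near-incompressible regime)",
         call. = FALSE)
  }
  structure(list(c10 = c10, c01 = c01, bulk_penalty = bulk_penalty),
            class = "mooney_rivlin")
}

#' @export
print.mooney_rivlin <- function(x, ...) {
  cat(sprintf("Mooney-Rivlin material: C10 = %g MPa, C01 = %g MPa, penalty = %g MPa\n",
              x$c10, x$c01, x$bulk_penalty))
  cat(sprintf("  shear modulus mu = %g MPa, equivalent Young's modulus 6*(C10+C01) = %g MPa\n",
              2 * (x$c10 + x$c01), 6 * (x$c10 + x$c01)))
  invisible(x)
}

#' Equivalent small-strain Young's modulus of a Mooney-Rivlin material
#'
#' For an incompressible Mooney-Rivlin solid the initial slope of the uniaxial
#' nominal stress-stretch curve is \eqn{E = 6(C_{10}+C_{01})}.
#'
#' @param params A [mooney_rivlin()] object.
#' @return Modulus in MPa.
#' @export
small_strain_modulus <- function(params) 6 * (params$c10 + params$c01)

#' Linear isotropic elastic parameters
#'
#' Used for the phantom holder (clamping ring), a stiff plastic part modeled as
#' linear isotropic elastic.
#'
#' @param youngs_modulus Young's modulus in MPa (> 0).
#' @param poisson_ratio Poisson ratio in `[0, 0.5)`.
#' @return An object of class `linear_elastic`.
#' @export
linear_elastic <- function(youngs_modulus, poisson_ratio = 0.3) {
  stopifnot(length(youngs_modulus) == 1L, length(poisson_ratio) == 1L)
  if (youngs_modulus <= 0) stop("youngs_modulus must be > 0", call. = FALSE)
  if (poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop("poisson_ratio must be in [0, 0.5)", call. = FALSE)
  }
  structure(list(youngs_modulus = youngs_modulus, poisson_ratio = poisson_ratio),
            class = "linear_elastic")
}

# Convert linear elastic constants to the hyperelastic (neo-Hookean + penalty)
# constants used internally by the element routines: same small-strain shear
# and bulk moduli. Holder strains are tiny so the models coincide there.
elastic_as_hyper <- function(le) {
  mu <- le$youngs_modulus / (2 * (1 + le$poisson_ratio))
  kappa <- le$youngs_modulus / (3 * (1 - 2 * le$poisson_ratio))
  list(c10 = mu / 2, c01 = 0, bulk_penalty = kappa)
}

#' Axisymmetric deformation state
#'
#' Wraps a deformation gradient and its invariants. The gradient is a 3x3
#' tensor; for axisymmetric kinematics the in-plane (r, z) block occupies
#' `F[1:2, 1:2]` and the hoop stretch `F[3, 3]`, but any 3x3 gradient with
#' positive determinant is accepted (rotation-appended states are used to test
#' objectivity).
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @return Object of class `deformation_state` with fields `F`, `J`, `I1`,
#'   `I2` (invariants of the left Cauchy-Green tensor `b = F F'`).
#' @export
deformation_state <- function(F) {
  F <- as.matrix(F)
  stopifnot(identical(dim(F), c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("invalid deformation state: det(F) <= 0", call. = FALSE)
  b <- F %*% t(F)
  I1 <- sum(diag(b))
  I2 <- 0.5 * (I1^2 - sum(b * b))
  structure(list(F = F, J = J, I1 = I1, I2 = I2), class = "deformation_state")
}

#' Strain-energy density
#'
#' Evaluates \eqn{W = C_{10}(\bar I_1-3) + C_{01}(\bar I_2-3) +
#' \kappa/2 (J-1)^2} with the isochoric invariants
#' \eqn{\bar I_1 = J^{-2/3} I_1}, \eqn{\bar I_2 = J^{-4/3} I_2}
#' (deviatoric/volumetric split).
#'
#' @param state A [deformation_state()].
#' @param params A [mooney_rivlin()] object.
#' @return Energy density in MPa.
#' @export
strain_energy <- function(state, params) {
  stopifnot(inherits(state, "deformation_state"))
  J <- state$J
  I1b <- J^(-2 / 3) * state$I1
  I2b <- J^(-4 / 3) * state$I2
  params$c10 * (I1b - 3) + params$c01 * (I2b - 3) +
    params$bulk_penalty / 2 * (J - 1)^2
}

## ---------------------------------------------------------------------------
## Vectorized Voigt machinery shared with the FE engine.
##
## Axisymmetric right Cauchy-Green tensor in the 4-component Voigt order
##   c = (C_rr, C_zz, C_tt, C_rz).
## With d = det C = C3*(C1*C2 - C4^2), J = sqrt(d),
##   I1 = C1 + C2 + C3,   I2 = C1*C2 + C1*C3 + C2*C3 - C4^2,
## the energy splits as
##   W_dev = c10*(I1*d^(-1/3) - 3) + c01*(I2*d^(-2/3) - 3)
##   W_vol = kappa/2*(sqrt(d) - 1)^2
## and gradient/Hessian w.r.t. c follow by the chain rule through (I1, I2, d),
## all of which are simple polynomials in c. `cm` is an n x 4 matrix so every
## quantity evaluates for all quadrature points at once.
## ---------------------------------------------------------------------------

mr_invariants <- function(cm) {
  C1 <- cm[, 1L]; C2 <- cm[, 2L]; C3 <- cm[, 3L]; C4 <- cm[, 4L]
  list(
    I1 = C1 + C2 + C3,
    I2 = C1 * C2 + C1 * C3 + C2 * C3 - C4^2,
    d  = C3 * (C1 * C2 - C4^2)
  )
}

# part: "dev", "vol" or "full"
mr_energy_c <- function(cm, c10, c01, kappa, part = "full") {
  iv <- mr_invariants(cm)
  w <- 0
  if (part != "vol") {
    w <- w + c10 * (iv$I1 * iv$d^(-1 / 3) - 3) + c01 * (iv$I2 * iv$d^(-2 / 3) - 3)
  }
  if (part != "dev") {
    w <- w + kappa / 2 * (sqrt(iv$d) - 1)^2
  }
  w
}

# gradient dW/dc, n x 4
mr_gradient_c <- function(cm, c10, c01, kappa, part = "full") {
  C1 <- cm[, 1L]; C2 <- cm[, 2L]; C3 <- cm[, 3L]; C4 <- cm[, 4L]
  iv <- mr_invariants(cm)
  I1 <- iv$I1; I2 <- iv$I2; d <- iv$d
  W_I1 <- 0; W_I2 <- 0; W_d <- 0
  if (part != "vol") {
    W_I1 <- c10 * d^(-1 / 3)
    W_I2 <- c01 * d^(-2 / 3)
    W_d <- W_d - (1 / 3) * c10 * I1 * d^(-4 / 3) - (2 / 3) * c01 * I2 * d^(-5 / 3)
  }
  if (part != "dev") {
    sd <- sqrt(d)
    W_d <- W_d + kappa * (sd - 1) / (2 * sd)
  }
  g <- matrix(0, nrow(cm), 4L)
  g[, 1L] <- W_I1 + W_I2 * (C2 + C3) + W_d * (C2 * C3)
  g[, 2L] <- W_I1 + W_I2 * (C1 + C3) + W_d * (C1 * C3)
  g[, 3L] <- W_I1 + W_I2 * (C1 + C2) + W_d * (C1 * C2 - C4^2)
  g[, 4L] <- W_I2 * (-2 * C4) + W_d * (-2 * C3 * C4)
  g
}

# Hessian d2W/dc2, n x 4 x 4 array
mr_hessian_c <- function(cm, c10, c01, kappa, part = "full") {
  n <- nrow(cm)
  C1 <- cm[, 1L]; C2 <- cm[, 2L]; C3 <- cm[, 3L]; C4 <- cm[, 4L]
  iv <- mr_invariants(cm)
  I1 <- iv$I1; I2 <- iv$I2; d <- iv$d

  W_I2 <- 0; W_d <- 0; W_dd <- 0; W_I1d <- 0; W_I2d <- 0
  if (part != "vol") {
    W_I2 <- c01 * d^(-2 / 3)
    W_d <- W_d - (1 / 3) * c10 * I1 * d^(-4 / 3) - (2 / 3) * c01 * I2 * d^(-5 / 3)
    W_I1d <- -(1 / 3) * c10 * d^(-4 / 3)
    W_I2d <- -(2 / 3) * c01 * d^(-5 / 3)
    W_dd <- W_dd + (4 / 9) * c10 * I1 * d^(-7 / 3) + (10 / 9) * c01 * I2 * d^(-8 / 3)
  }
  if (part != "dev") {
    sd <- sqrt(d)
    W_d <- W_d + kappa * (sd - 1) / (2 * sd)
    W_dd <- W_dd + kappa / (4 * d^1.5)
  }

  gI1 <- cbind(1, 1, 1, 0)[rep(1L, n), , drop = FALSE]
  gI2 <- cbind(C2 + C3, C1 + C3, C1 + C2, -2 * C4)
  gd  <- cbind(C2 * C3, C1 * C3, C1 * C2 - C4^2, -2 * C3 * C4)

  H <- array(0, dim = c(n, 4L, 4L))
  # rank-one chain-rule terms
  for (a in 1:4) for (b in 1:4) {
    H[, a, b] <- W_dd * gd[, a] * gd[, b] +
      W_I1d * (gI1[, a] * gd[, b] + gd[, a] * gI1[, b]) +
      W_I2d * (gI2[, a] * gd[, b] + gd[, a] * gI2[, b])
  }
  # Hessian of I2 (constant)
  H[, 1, 2] <- H[, 1, 2] + W_I2; H[, 2, 1] <- H[, 2, 1] + W_I2
  H[, 1, 3] <- H[, 1, 3] + W_I2; H[, 3, 1] <- H[, 3, 1] + W_I2
  H[, 2, 3] <- H[, 2, 3] + W_I2; H[, 3, 2] <- H[, 3, 2] + W_I2
  H[, 4, 4] <- H[, 4, 4] - 2 * W_I2
  # Hessian of d
  H[, 1, 2] <- H[, 1, 2] + W_d * C3; H[, 2, 1] <- H[, 2, 1] + W_d * C3
  H[, 1, 3] <- H[, 1, 3] + W_d * C2; H[, 3, 1] <- H[, 3, 1] + W_d * C2
  H[, 2, 3] <- H[, 2, 3] + W_d * C1; H[, 3, 2] <- H[, 3, 2] + W_d * C1
  H[, 3, 4] <- H[, 3, 4] - 2 * W_d * C4; H[, 4, 3] <- H[, 4, 3] - 2 * W_d * C4
  H[, 4, 4] <- H[, 4, 4] - 2 * W_d * C3
  H
}

#' Stress and consistent tangent of the Mooney-Rivlin model
#'
#' Differentiates the strain energy at an axisymmetric deformation state:
#' returns the second Piola-Kirchhoff stress, the Cauchy stress
#' \eqn{\sigma = J^{-1} F S F^T}, and the material tangent
#' \eqn{D = \partial S/\partial E} in Voigt order
#' `(rr, zz, hoop, rz)` with engineering shear strain. Both stress tensors and
#' the tangent are symmetric; the tangent is the exact linearization used by
#' the Newton solver.
#'
#' @param state A [deformation_state()] whose gradient is axisymmetric
#'   (no coupling between the hoop direction and the (r, z) plane).
#' @param params A [mooney_rivlin()] object (or plain list with `c10`, `c01`,
#'   `bulk_penalty`).
#' @return List with `S` (3x3 PK2 stress, MPa), `cauchy` (3x3, MPa) and
#'   `tangent` (4x4 Voigt material tangent, MPa).
#' @export
constitutive_update <- function(state, params) {
  stopifnot(inherits(state, "deformation_state"))
  F <- state$F
  if (max(abs(c(F[1, 3], F[2, 3], F[3, 1], F[3, 2]))) > 1e-12) {
    stop("constitutive_update expects an axisymmetric gradient (no hoop coupling)",
         call. = FALSE)
  }
  C <- t(F) %*% F
  cm <- matrix(c(C[1, 1], C[2, 2], C[3, 3], C[1, 2]), 1L, 4L)
  g <- mr_gradient_c(cm, params$c10, params$c01, params$bulk_penalty)
  H <- mr_hessian_c(cm, params$c10, params$c01, params$bulk_penalty)
  S <- matrix(0, 3, 3)
  S[1, 1] <- 2 * g[1, 1]; S[2, 2] <- 2 * g[1, 2]; S[3, 3] <- 2 * g[1, 3]
  S[1, 2] <- S[2, 1] <- g[1, 4]
  cauchy <- F %*% S %*% t(F) / state$J
  # chain rule c -> e = (E11, E22, E33, gamma12): dc/de = diag(2, 2, 2, 1),
  # and s = (2 g1, 2 g2, 2 g3, g4), so D = M H M with M = diag(2, 2, 2, 1)
  M <- diag(c(2, 2, 2, 1))
  D <- M %*% H[1, , ] %*% M
  list(S = S, cauchy = cauchy, tangent = (D + t(D)) / 2)
}

#' Closed-form uniaxial nominal stress of an incompressible Mooney-Rivlin solid
#'
#' Exact incompressible solution for uniaxial tension along one axis with free
#' lateral surfaces: nominal (first Piola-Kirchhoff / engineering) stress
#' \deqn{P(\lambda) = 2 (\lambda - \lambda^{-2}) (C_{10} + C_{01}/\lambda).}
#' The volumetric penalty plays no role (isochoric deformation). This is the
#' analytic oracle the FE strip simulation is checked against.
#'
#' @param stretch Stretch ratio(s) \eqn{\lambda > 0}; vectorized.
#' @param params A [mooney_rivlin()] object.
#' @return Nominal stress in MPa (vector like `stretch`).
#' @export
uniaxial_nominal_stress <- function(stretch, params) {
  if (any(stretch <= 0)) stop("stretch must be positive", call. = FALSE)
  2 * (stretch - stretch^-2) * (params$c10 + params$c01 / stretch)
}
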