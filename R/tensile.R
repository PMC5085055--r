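#' Uniaxial tensile-test specimen specification
#'
#' Strip-specimen geometry and sampling for the simulated uniaxial tensile
#' test. Defaults follow standard hydrogel strip extensiometry: a 3 mm wide,
#' 0.55 mm thick strip with 12 mm free length between the clamps.
#'
#' @param free_length Free length between clamps, mm.
#' @param width Strip width, mm.
#' @param thickness Strip thickness, mm.
#' @param max_strain Maximum engineering strain (in `(0, 1.5]`).
#' @param n_points Number of curve samples (uniform in strain, from 0).
#' @param rate Loading rate in mm/s; recorded as metadata only (the material
#'   model is purely elastic, so the rate has no effect on the curve).
#' @return Object of class `tensile_spec`.
#' @export
tensile_spec <- function(free_length = 12, width = 3, thickness = 0.55,
                         max_strain = 0.4, n_points = 81L, rate = 1) {
  stopifnot(free_length > 0, width > 0, thickness > 0,
            max_strain > 0, max_strain <= 1.5, n_points >= 2L)
  structure(list(free_length = free_length, width = width,
                 thickness = thickness, max_strain = max_strain,
                 n_points = as.integer(n_points), rate = rate),
            class = "tensile_spec")
}

#' Stress-strain curve container
#'
#' @param strain Engineering strain, strictly increasing from 0.
#' @param stress Nominal stress in MPa; `stress[1]` must be 0 at zero strain.
#' @return Object of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(strain, stress) {
  stopifnot(length(strain) == length(stress), length(strain) >= 2L)
  if (strain[1L] != 0 || any(diff(strain) <= 0)) {
    stop("strain must be strictly increasing from 0", call. = FALSE)
  }
  if (abs(stress[1L]) > 1e-12) stop("stress at zero strain must be 0", call. = FALSE)
  structure(list(strain = strain, stress = stress), class = "stress_strain_curve")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("stress-strain curve: %d points, strain 0..%.3g, max stress %.4g MPa\n",
              length(x$strain), max(x$strain), max(x$stress)))
  invisible(x)
}

#' Simulate the uniaxial tensile test
#'
#' Produces the nominal stress vs engineering strain curve of a Mooney-Rivlin
#' strip. The default path evaluates the exact incompressible closed form
#' [uniaxial_nominal_stress()]; `method = "fe"` instead runs the nonlinear
#' finite-element engine on an axisymmetric rod of equal cross-sectional area
#' stretched between prescribed end displacements — a homogeneous uniaxial
#' state is independent of the cross-section shape, so the rod reproduces the
#' strip exactly and serves as a cross-check of the engine against the closed
#' form.
#'
#' @param params [mooney_rivlin()] material.
#' @param spec A [tensile_spec()].
#' @param method `"closed_form"` (default) or `"fe"`.
#' @return A [stress_strain_curve()].
#' @export
simulate_tensile <- function(params, spec = tensile_spec(),
                             method = c("closed_form", "fe")) {
  method <- match.arg(method)
  eps <- seq(0, spec$max_strain, length.out = spec$n_points)
  if (method == "closed_form") {
    sigma <- uniaxial_nominal_stress(1 + eps, params)
  } else {
    sigma <- fe_tensile_stress(params, spec, eps)
  }
  stress_strain_curve(eps, sigma)
}

# FE strip mode: axisymmetric rod, radius matching the strip cross-section
# area, pulled by prescribed end displacement; nominal stress = end reaction
# divided by the reference area.
fe_tensile_stress <- function(params, spec, eps, nr = 2L, nz = 6L) {
  r_eq <- sqrt(spec$width * spec$thickness / pi)
  L <- spec$free_length
  rg <- seq(0, r_eq, length.out = nr + 1L)
  zg <- seq(0, L, length.out = nz + 1L)
  nodes <- cbind(rep(rg, times = nz + 1L), rep(zg, each = nr + 1L))
  nid <- function(i, j) j * (nr + 1L) + i + 1L
  elem <- matrix(0L, nr * nz, 4L)
  e <- 0L
  for (j in 0:(nz - 1L)) for (i in 0:(nr - 1L)) {
    e <- e + 1L
    elem[e, ] <- c(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L), nid(i, j + 1L))
  }
  axis_nodes <- nid(0L, 0:nz)
  bot <- nid(0:nr, 0L)
  top <- nid(0:nr, nz)
  area <- pi * r_eq^2

  sigma <- numeric(length(eps))
  u0 <- NULL
  for (k in seq_along(eps)) {
    if (eps[k] == 0) next
    fixed <- c(2L * axis_nodes - 1L, 2L * bot, 2L * top)
    vals <- c(numeric(length(axis_nodes)), numeric(length(bot)),
              rep(eps[k] * L, length(top)))
    pb <- fe_problem(nodes, elem,
                     c10 = rep(params$c10, nrow(elem)),
                     c01 = rep(params$c01, nrow(elem)),
                     kappa = rep(params$bulk_penalty, nrow(elem)),
                     fixed_dofs = fixed, fixed_vals = vals)
    sol <- fe_solve(pb, n_increments = if (is.null(u0)) 2L else 1L, u0 = u0)
    u0 <- sol$u_flat
    f_int <- fe_internal(pb, sol$u_flat)$f
    sigma[k] <- sum(f_int[2L * top]) / area
  }
  sigma
}

#' Equivalent Young's modulus of a stress-strain curve
#'
#' The average slope of the curve over the 0-0.1 strain range, implemented as
#' the secant \eqn{(\sigma(0.1) - \sigma(0)) / 0.1} with \eqn{\sigma(0.1)}
#' linearly interpolated (`method = "secant"`, default), or as the ordinary
#' least-squares slope through all samples in the range (`method = "ols"`);
#' the two agree to about 1% for the mild curvature of corneal hydrogels.
#'
#' @param curve A [stress_strain_curve()] (or two-column object) covering
#'   strain `[0, strain_limit]`.
#' @param strain_limit Upper end of the averaging range (default 0.1).
#' @param method `"secant"` or `"ols"`.
#' @return Modulus in MPa.
#' @export
equivalent_youngs_modulus <- function(curve, strain_limit = 0.1,
                                      method = c("secant", "ols")) {
  method <- match.arg(method)
  m <- curve_matrix(curve)
  if (max(m[, 1L]) < strain_limit - 1e-12 || min(m[, 1L]) > 1e-12) {
    stop(sprintf("curve must cover the strain range [0, %g]", strain_limit),
         call. = FALSE)
  }
  if (method == "secant") {
    s0 <- stats::approx(m[, 1L], m[, 2L], xout = 0)$y
    s1 <- stats::approx(m[, 1L], m[, 2L], xout = strain_limit)$y
    (s1 - s0) / strain_limit
  } else {
    sel <- m[, 1L] <= strain_limit + 1e-12
    unname(stats::coef(stats::lm(m[sel, 2L] ~ m[sel, 1L]))[2L])
  }
}

#' Truncate a stress-strain curve at experimental stop conditions
#'
#' Mirrors how strip tests are stopped in practice: at a maximum crosshead
#' extension and/or a maximum force, whichever comes first.
#'
#' @param curve A [stress_strain_curve()].
#' @param spec The [tensile_spec()] describing the strip.
#' @param max_extension Maximum extension in mm, or `NULL`.
#' @param max_force Maximum force in N, or `NULL`.
#' @return The truncated [stress_strain_curve()].
#' @export
truncate_curve <- function(curve, spec, max_extension = NULL, max_force = NULL) {
  keep <- rep(TRUE, length(curve$strain))
  if (!is.null(max_extension)) {
    keep <- keep & (curve$strain * spec$free_length <= max_extension + 1e-12)
  }
  if (!is.null(max_force)) {
    force <- curve$stress * spec$width * spec$thickness
    keep <- keep & (force <= max_force + 1e-12)
  }
  if (sum(keep) < 2L) stop("truncation leaves fewer than 2 points", call. = FALSE)
  stress_strain_curve(curve$strain[keep], curve$stress[keep])
}
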