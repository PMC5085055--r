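#' Air-pulse load model
#'
#' Parameterized spatio-temporal pressure model of the instrument's air pulse:
#' a Gaussian radial footprint and a unit-amplitude temporal bell,
#' \deqn{p(r, t) = p_{peak}\, e^{-r^2 / (2\sigma^2)}\, s(t),}
#' with \eqn{s(t) = \sin^2(\pi t / T)} by default (peaking at \eqn{T/2}).
#' The defaults are a calibrated stand-in for the instrument's measured
#' pressure distribution: `peak_pressure` is chosen so that hydrogel phantoms
#' spanning manufacturer moduli 0.16-0.38 MPa and thicknesses 350-550 um
#' deform by roughly 0.7-1.6 mm, the deformation-amplitude envelope such
#' phantoms show under a Corvis-type pulse. A tabulated radial footprint can
#' be substituted via `footprint`.
#'
#' @param peak_pressure Peak pressure in MPa (default 0.0045 = 4.5 kPa).
#' @param spatial_sigma Gaussian radial decay length in mm.
#' @param duration Pulse duration in ms (default 30).
#' @param n_frames Number of recorded frames over the pulse (default 140,
#'   i.e. about 4.33 frames/ms).
#' @param temporal_shape Function of `t` (ms) on `[0, duration]` returning the
#'   unit-amplitude temporal profile; values must lie in `[0, 1]` with max 1.
#' @param footprint Optional two-column matrix/data frame `(r_mm,
#'   relative_pressure)`; when given, the relative radial profile is linearly
#'   interpolated from it instead of the Gaussian (clamped to 0 beyond the
#'   table).
#' @return Object of class `airpuff_load`.
#' @export
airpuff_load <- function(peak_pressure = 0.0045, spatial_sigma = 1.5,
                         duration = 30, n_frames = 140L,
                         temporal_shape = NULL, footprint = NULL) {
  stopifnot(peak_pressure >= 0, spatial_sigma > 0, duration > 0, n_frames >= 3L)
  if (is.null(temporal_shape)) {
    temporal_shape <- local({
      Tdur <- duration
      function(t) sin(pi * t / Tdur)^2
    })
  }
  if (!is.null(footprint)) {
    footprint <- as.matrix(footprint)
    stopifnot(ncol(footprint) == 2L, nrow(footprint) >= 2L)
  }
  structure(list(peak_pressure = peak_pressure, spatial_sigma = spatial_sigma,
                 duration = duration, n_frames = as.integer(n_frames),
                 temporal_shape = temporal_shape, footprint = footprint),
            class = "airpuff_load")
}

#' Instantaneous air-pulse pressure
#'
#' @param r Radial position(s) from the jet axis, mm.
#' @param t Time since pulse start, ms; must lie in `[0, duration]`.
#' @param load An [airpuff_load()].
#' @return Pressure in MPa.
#' @export
pressure_at <- function(r, t, load) {
  stopifnot(inherits(load, "airpuff_load"))
  if (any(t < 0 | t > load$duration)) stop("t outside the pulse duration", call. = FALSE)
  rel <- if (is.null(load$footprint)) {
    exp(-r^2 / (2 * load$spatial_sigma^2))
  } else {
    stats::approx(load$footprint[, 1L], load$footprint[, 2L], xout = r,
                  yleft = load$footprint[1L, 2L], yright = 0)$y
  }
  load$peak_pressure * rel * load$temporal_shape(t)
}

# spatial profile of the pulse at its temporal peak, as a function of r
puff_field <- function(load, t) {
  force(load); force(t)
  function(r) pressure_at(r, t, load)
}

#' Forward air-puff experiment
#'
#' Runs the full forward model: quasi-static inflation of the cornea to the
#' intraocular pressure, then a sweep of the air pulse in time with one
#' converged equilibrium solve per frame (the pulse pressure is held as an
#' instantaneous follower load; the IOP stays applied throughout). All
#' displacements are reported relative to the inflated, pre-puff state, which
#' is what the instrument images before the pulse.
#'
#' @param geom A [cornea_geometry()].
#' @param material [mooney_rivlin()] cornea parameters.
#' @param iop Intraocular pressure in mmHg (default 15).
#' @param load An [airpuff_load()].
#' @param frames `"all"` computes every frame of the pulse; `"hc"` computes
#'   only the highest-concavity frame (at the pulse peak; valid because the
#'   quasi-static elastic response is a monotone function of the instantaneous
#'   load) plus the zero-deformation endpoints, which is all the deformation
#'   metrics require and is the fast path used inside the inverse loop.
#' @param mesh Optional prebuilt mesh; default `build_mesh(geom, 4, 100)`.
#' @param lateral_grid Fixed lateral sampling grid (mm) for the surface
#'   profiles, symmetric about 0.
#' @param tol,n_increments Solver controls passed to the static solver.
#' @param cache Optional environment used to warm-start the nonlinear solves
#'   across repeated calls with the same mesh (e.g. inside the inverse loop).
#' @return A `deformation_record`: frame times (ms), the fixed lateral grid,
#'   per-frame anterior-surface heights (mm), the pre-puff reference profile,
#'   and the apex displacement trace (mm, positive into the eye).
#' @export
simulate_airpuff <- function(geom, material, iop = 15, load = airpuff_load(),
                             frames = c("all", "hc"), mesh = NULL,
                             lateral_grid = seq(-4, 4, by = 0.05),
                             tol = 1e-6, n_increments = 5L, cache = NULL) {
  frames <- match.arg(frames)
  stopifnot(inherits(geom, "cornea_geometry"), inherits(load, "airpuff_load"))
  if (is.null(mesh)) mesh <- build_mesh(geom)
  iop_mpa <- mmhg_to_mpa(iop)
  holder <- geom$holder_material

  # stage 1: inflation to IOP (warm-started when a cache is supplied)
  pb_inf <- cornea_problem(mesh, material, holder, load_case(iop_mpa))
  u_inf0 <- if (!is.null(cache) && !is.null(cache$u_inf)) cache$u_inf else NULL
  sol_inf <- if (is.null(u_inf0)) {
    fe_solve(pb_inf, n_increments = 4L, tol = tol)
  } else {
    tryCatch(fe_solve(pb_inf, n_increments = 1L, tol = tol, u0 = u_inf0),
             ap_nonconvergence = function(e) fe_solve(pb_inf, n_increments = 4L, tol = tol))
  }
  if (!is.null(cache)) cache$u_inf <- sol_inf$u_flat

  times <- if (frames == "all") {
    seq(0, load$duration, length.out = load$n_frames)
  } else {
    c(0, load$duration / 2, load$duration)
  }

  ant <- mesh$sets$anterior_nodes
  ref_prof <- surface_heights(mesh, sol_inf$u_flat, ant, lateral_grid)
  apex <- mesh$sets$apex_anterior
  z_apex_ref <- mesh$nodes[apex, 2L] + sol_inf$u_flat[2L * apex]

  nfr <- length(times)
  heights <- matrix(NA_real_, nfr, length(lateral_grid))
  apex_disp <- numeric(nfr)
  u_prev <- sol_inf$u_flat
  u_prev2 <- NULL # state two frames back, for extrapolated warm starts
  u_peak_start <- if (!is.null(cache)) cache$u_peak else NULL

  for (k in seq_len(nfr)) {
    tk <- times[k]
    amp <- load$temporal_shape(tk)
    if (amp * load$peak_pressure <= 0) {
      heights[k, ] <- ref_prof
      apex_disp[k] <- 0
      u_prev2 <- u_prev
      next
    }
    lc <- load_case(iop_mpa, puff_field(load, tk))
    pb <- cornea_problem(mesh, material, holder, lc, ramp_internal = FALSE)
    u0 <- if (!is.null(u_prev2)) 2 * u_prev - u_prev2 else u_prev
    if (frames == "hc" && !is.null(u_peak_start)) u0 <- u_peak_start
    sol <- tryCatch(
      fe_solve(pb, n_increments = 1L, tol = tol, u0 = u0),
      ap_nonconvergence = function(e) {
        tryCatch(fe_solve(pb, n_increments = n_increments, tol = tol,
                          u0 = sol_inf$u_flat),
                 ap_nonconvergence = function(e2) {
                   stop(structure(class = c("ap_nonconvergence", "error", "condition"),
                                  list(message = sprintf(
                                    "air-puff frame %d (t = %.2f ms) did not converge: %s",
                                    k, tk, conditionMessage(e2)),
                                    call = NULL, frame = k)))
                 })
      })
    u_prev2 <- u_prev
    u_prev <- sol$u_flat
    if (!is.null(cache) && abs(tk - load$duration / 2) < 1e-9) {
      cache$u_peak <- sol$u_flat
    }
    heights[k, ] <- surface_heights(mesh, sol$u_flat, ant, lateral_grid)
    apex_disp[k] <- z_apex_ref - (mesh$nodes[apex, 2L] + sol$u_flat[2L * apex])
  }

  new_deformation_record(times = times, grid = lateral_grid, heights = heights,
                         reference = ref_prof, apex_disp = apex_disp,
                         reduced = FALSE,
                         meta = list(iop_mmhg = iop, frames = frames))
}

# anterior-surface height z(|x|) sampled on the fixed lateral grid, mirrored
# about the axis (axisymmetry)
surface_heights <- function(mesh, u_flat, ant_nodes, grid) {
  r_cur <- mesh$nodes[ant_nodes, 1L] + u_flat[2L * ant_nodes - 1L]
  z_cur <- mesh$nodes[ant_nodes, 2L] + u_flat[2L * ant_nodes]
  ord <- order(r_cur)
  stats::approx(r_cur[ord], z_cur[ord], xout = abs(grid), rule = 2)$y
}

new_deformation_record <- function(times, grid, heights, reference, apex_disp,
                                   reduced = FALSE, meta = list()) {
  structure(list(times = times, grid = grid, heights = heights,
                 reference = reference, apex_disp = apex_disp,
                 reduced = reduced, meta = meta),
            class = "deformation_record")
}

#' @export
print.deformation_record <- function(x, ...) {
  cat(sprintf("deformation record: %d frames over %.1f ms, lateral grid %+.1f..%+.1f mm (%d pts)%s\n",
              length(x$times), max(x$times), min(x$grid), max(x$grid),
              length(x$grid), if (x$reduced) " [reduced]" else ""))
  cat(sprintf("  max apex displacement %.3f mm\n", max(x$apex_disp)))
  invisible(x)
}

#' Unit conversion between mmHg and MPa
#'
#' 1 mmHg = 133.322 Pa = 1.33322e-4 MPa.
#' @param x Pressure value(s).
#' @return Converted value(s).
#' @export
mmhg_to_mpa <- function(x) x * 133.322e-6

#' @rdname mmhg_to_mpa
#' @export
mpa_to_mmhg <- function(x) x / 133.322e-6
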