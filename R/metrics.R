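#' Deformation parameters of an air-puff record
#'
#' Computes the standard air-puff deformation parameters from a deformation
#' record: highest concavity (HC) is the frame of maximal apex displacement;
#' `DA` is the apex displacement there (central deformation amplitude, mm);
#' `PDA` the mean displacement linearly interpolated at exactly -2 and +2 mm
#' lateral from the apex in the HC frame (peripheral deformation amplitude,
#' mm); `CPR = DA / PDA` (central-peripheral deformation ratio); and `THC` the
#' time from pulse start to HC (ms).
#'
#' To make the peak estimate robust to frame-to-frame measurement noise, the
#' apex value and time at HC are refined by a local quadratic fit of the apex
#' trace around the discrete maximum (window of up to 2 frames each side).
#' For noiseless, symmetric traces the refinement is exact at the peak and
#' changes nothing.
#'
#' @param record A `deformation_record` (from [simulate_airpuff()],
#'   [read_deformation_record()] or the synthetic generator).
#' @return Object of class `deformation_metrics` with fields `DA`, `PDA`,
#'   `CPR`, `THC`.
#' @export
compute_metrics <- function(record) {
  stopifnot(inherits(record, "deformation_record"))
  n <- length(record$times)
  if (n < 3L) stop("record must contain at least 3 frames", call. = FALSE)
  if (max(record$grid) < 2 || min(record$grid) > -2) {
    stop("lateral grid must span at least +/-2 mm", call. = FALSE)
  }

  trace <- record$apex_disp
  hc <- which.max(trace)
  pk <- quad_peak(record$times, trace, hc)
  DA <- pk$value
  THC <- pk$time

  disp <- if (record$reduced) {
    record$reference - record$hc_profile
  } else {
    record$reference - record$heights[hc, ]
  }
  d2 <- stats::approx(record$grid, disp, xout = c(-2, 2))$y
  PDA <- mean(d2)
  if (DA > 0 && PDA <= 0) {
    stop("degenerate profile: PDA <= 0 with DA > 0", call. = FALSE)
  }
  CPR <- if (DA == 0 && PDA == 0) 1 else DA / PDA
  structure(list(DA = DA, PDA = PDA, CPR = CPR, THC = THC),
            class = "deformation_metrics")
}

# local quadratic refinement of a discrete peak; falls back to the raw sample
# when the window is degenerate or the fit is not concave
quad_peak <- function(t, y, i) {
  n <- length(y)
  lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
  if (hi - lo < 2L) return(list(value = y[i], time = t[i]))
  tw <- t[lo:hi]; yw <- y[lo:hi]
  fit <- stats::lm.fit(cbind(1, tw, tw^2), yw)
  a <- fit$coefficients
  if (!is.finite(a[3L]) || a[3L] >= 0) return(list(value = y[i], time = t[i]))
  tv <- -a[2L] / (2 * a[3L])
  tv <- min(max(tv, t[lo]), t[hi])
  list(value = unname(a[1L] + a[2L] * tv + a[3L] * tv^2), time = unname(tv))
}

#' @export
print.deformation_metrics <- function(x, ...) {
  cat(sprintf("DA = %.4f mm, PDA = %.4f mm, CPR = %.4f, THC = %.2f ms\n",
              x$DA, x$PDA, x$CPR, x$THC))
  invisible(x)
}

#' Inverse-fit merit function
#'
#' Scalar mismatch between measured and simulated deformation parameters,
#' \deqn{\Phi = |DA_m - DA_{sim}| + w\,|CPR_m - CPR_{sim}|,}
#' with the dimensionless CPR term down-weighted by `weight_cpr` (default
#' 1/3). The merit is zero exactly when DA and CPR both agree, so any
#' positive weight yields the same optimum when an exact fit exists; the
#' weight only matters under model mismatch.
#'
#' @param measured,simulated `deformation_metrics` objects.
#' @param weight_cpr Weight of the CPR residual.
#' @return Non-negative dimensionless merit (the DA term carries mm).
#' @export
merit <- function(measured, simulated, weight_cpr = 1 / 3) {
  stopifnot(inherits(measured, "deformation_metrics"),
            inherits(simulated, "deformation_metrics"))
  abs(measured$DA - simulated$DA) + weight_cpr * abs(measured$CPR - simulated$CPR)
}

#' Root-mean-square difference between two profiles
#'
#' Resamples both profiles onto a shared uniform grid over the overlap of
#' their supports by linear interpolation and returns the RMS of the
#' pointwise differences. Used for spatial deformation profiles (lateral
#' position vs height or displacement) and temporal profiles (time vs apex
#' displacement) alike.
#'
#' @param a,b Two-column matrices or data frames `(x, y)`.
#' @param window Optional `c(lo, hi)` restricting the comparison (e.g.
#'   `c(-4, 4)` mm for spatial profiles); intersected with the common support.
#' @param n Number of shared grid points.
#' @return RMS difference in the profiles' y units (mm).
#' @export
profile_rms <- function(a, b, window = NULL, n = 201L) {
  a <- as.matrix(a); b <- as.matrix(b)
  lo <- max(min(a[, 1L]), min(b[, 1L]))
  hi <- min(max(a[, 1L]), max(b[, 1L]))
  if (!is.null(window)) {
    lo <- max(lo, window[1L]); hi <- min(hi, window[2L])
  }
  if (hi <= lo) stop("profiles have no overlapping support", call. = FALSE)
  x <- seq(lo, hi, length.out = n)
  ya <- stats::approx(a[, 1L], a[, 2L], xout = x)$y
  yb <- stats::approx(b[, 1L], b[, 2L], xout = x)$y
  sqrt(mean((ya - yb)^2))
}

#' Point-to-point correspondence of two stress-strain curves
#'
#' Percent agreement defined as 100 times one minus the mean relative
#' deviation over a uniform strain grid,
#' \deqn{100\,(1 - \mathrm{mean}_\varepsilon\; |\sigma_{test} -
#'   \sigma_{ref}| / \max(|\sigma_{ref}|, f)),}
#' where the floor \eqn{f} is 1% of the maximal reference stress over the
#' range, guarding the zero-stress origin.
#'
#' @param reference,test Stress-strain curves: two-column objects
#'   `(strain, stress_MPa)` or [stress_strain_curve()] objects.
#' @param strain_range `c(lo, hi)` strain interval; default the overlap of
#'   the two curves.
#' @param n_grid Number of uniform grid points.
#' @return Correspondence in percent (can be negative for grossly different
#'   curves).
#' @export
correspondence <- function(reference, test, strain_range = NULL, n_grid = 81L) {
  reference <- curve_matrix(reference)
  test <- curve_matrix(test)
  lo <- max(min(reference[, 1L]), min(test[, 1L]))
  hi <- min(max(reference[, 1L]), max(test[, 1L]))
  if (!is.null(strain_range)) {
    if (strain_range[1L] < lo - 1e-12 || strain_range[2L] > hi + 1e-12) {
      stop("curves do not cover the requested strain_range", call. = FALSE)
    }
    lo <- strain_range[1L]; hi <- strain_range[2L]
  }
  if (hi <= lo) stop("curves have no overlapping strain support", call. = FALSE)
  eps <- seq(lo, hi, length.out = n_grid)
  sr <- stats::approx(reference[, 1L], reference[, 2L], xout = eps)$y
  st <- stats::approx(test[, 1L], test[, 2L], xout = eps)$y
  floor_ <- 0.01 * max(abs(sr))
  100 * (1 - mean(abs(st - sr) / pmax(abs(sr), floor_)))
}

curve_matrix <- function(x) {
  if (inherits(x, "stress_strain_curve")) {
    cbind(x$strain, x$stress)
  } else {
    as.matrix(x)
  }
}
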