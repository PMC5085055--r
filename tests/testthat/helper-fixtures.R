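# shared fixtures: small geometries/meshes keep the unit tests fast; the
# acceptance suite uses the full-resolution defaults

tiny_geom <- function(thickness = 0.45) {
  cornea_geometry(posterior_radius = 8.60, thickness = thickness)
}

tiny_mesh <- function(geom = tiny_geom(), nt = 2L, nm = 24L, nh = 4L) {
  build_mesh(geom, nt, nm, nh)
}

# random axisymmetric deformation gradient with moderate strain
random_axisym_F <- function() {
  F <- diag(3)
  F[1, 1] <- 1 + stats::runif(1, -0.15, 0.3)
  F[2, 2] <- 1 + stats::runif(1, -0.15, 0.3)
  F[3, 3] <- 1 + stats::runif(1, -0.15, 0.3)
  F[1, 2] <- stats::runif(1, -0.2, 0.2)
  F[2, 1] <- stats::runif(1, -0.2, 0.2)
  F
}

# analytic deformation record: quadratic-in-time bell, Gaussian-in-space dip
analytic_record <- function(n_frames = 140L, duration = 30,
                            da = 1.2, d2mm = 0.8,
                            grid = seq(-4, 4, by = 0.05),
                            peak_frame = NULL) {
  times <- seq(0, duration, length.out = n_frames)
  shape <- sin(pi * times / duration)^2
  if (!is.null(peak_frame)) {
    # shift so the discrete maximum lands on the requested frame
    shape <- shape * 0
    shape[peak_frame] <- 1
    w <- 6L
    for (k in seq_along(times)) {
      d <- abs(k - peak_frame)
      if (d > 0 && d <= w) shape[k] <- 1 - (d / (w + 1))^2
    }
  }
  # spatial displacement shape: da at 0, d2mm at +/-2
  sigma2 <- -4 / (2 * log(d2mm / da))
  prof <- da * exp(-grid^2 / (2 * sigma2))
  ref <- 10 - grid^2 / 18 # spherical-ish cap
  heights <- t(vapply(shape, function(s) ref - s * prof, numeric(length(grid))))
  i0 <- which.min(abs(grid))
  rec <- airpuffr:::new_deformation_record(
    times = times, grid = grid, heights = heights, reference = ref,
    apex_disp = shape * prof[i0], reduced = FALSE)
  rec
}

# deterministic circular-plate bending problem (volumetric locking guard)
plate_problem <- function(nr = 60L, nzt = 3L, a = 5, th = 0.2, p = 2e-6,
                          mat = mooney_rivlin(0.25, 0)) {
  rg <- seq(0, a, length.out = nr + 1L)
  zg <- seq(0, th, length.out = nzt + 1L)
  nodes <- cbind(rep(rg, times = nzt + 1L), rep(zg, each = nr + 1L))
  nid <- function(i, j) j * (nr + 1L) + i + 1L
  elem <- matrix(0L, nr * nzt, 4L)
  e <- 0L
  for (j in 0:(nzt - 1L)) for (i in 0:(nr - 1L)) {
    e <- e + 1L
    elem[e, ] <- c(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L), nid(i, j + 1L))
  }
  axisn <- nid(0L, 0:nzt)
  outer <- nid(nr, 0:nzt)
  fixed <- c(2L * axisn - 1L, 2L * outer - 1L, 2L * outer)
  topedges <- cbind(nid(1:nr, nzt), nid(0:(nr - 1L), nzt))
  pb <- airpuffr:::fe_problem(nodes, elem,
                              c10 = rep(mat$c10, e), c01 = rep(mat$c01, e),
                              kappa = rep(mat$bulk_penalty, e),
                              fixed_dofs = fixed,
                              edge_loads = list(list(edges = topedges,
                                                     p = rep(p, nr))))
  list(pb = pb, center_node = nid(0L, 0L), a = a, th = th, p = p, mat = mat)
}
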