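#' Parametric cornea + holder geometry
#'
#' Describes a spherical-cap cornea (or hydrogel phantom) of uniform thickness
#' clamped in an artificial-chamber holder. The anterior and posterior surfaces
#' are concentric spheres, so `anterior_radius = posterior_radius + thickness`
#' holds exactly; supplying an inconsistent triple is a configuration error.
#'
#' Coordinates: `z` along the symmetry/air-jet axis, positive toward the air
#' nozzle; `r` is the distance from the axis. Displacements are reported
#' positive when the surface moves away from the nozzle (into the eye).
#'
#' @param posterior_radius Posterior radius of curvature in mm.
#' @param thickness Corneal thickness in mm (uniform).
#' @param anterior_radius Anterior radius of curvature in mm; defaults to
#'   `posterior_radius + thickness` and must equal it to within 1e-6 mm.
#' @param aperture_radius Inner radius of the holder clamp opening in mm.
#' @param holder_material [linear_elastic()] parameters of the holder ring.
#' @param holder_width Radial width of the meshed holder flange in mm.
#' @return Object of class `cornea_geometry`.
#' @examples
#' cornea_geometry(thickness = 0.55) # the thickest phantom: 8.60 / 9.15 mm
#' @export
cornea_geometry <- function(posterior_radius = 8.60, thickness = 0.55,
                            anterior_radius = posterior_radius + thickness,
                            aperture_radius = 5.5,
                            holder_material = linear_elastic(1500, 0.3),
                            holder_width = 2) {
  err <- function(msg) stop(structure(
    class = c("ap_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
  if (posterior_radius <= 0 || thickness <= 0) err("radii and thickness must be positive")
  if (abs(anterior_radius - posterior_radius - thickness) > 1e-6) {
    err("anterior_radius must equal posterior_radius + thickness (concentric spheres)")
  }
  if (aperture_radius <= 0 || aperture_radius >= anterior_radius) {
    err("aperture_radius must lie in (0, anterior_radius)")
  }
  if (aperture_radius + holder_width >= posterior_radius + thickness / 2) {
    err("holder flange extends beyond the equator of the corneal sphere")
  }
  structure(list(posterior_radius = posterior_radius,
                 anterior_radius = anterior_radius,
                 thickness = thickness,
                 aperture_radius = aperture_radius,
                 holder_material = holder_material,
                 holder_width = holder_width),
            class = "cornea_geometry")
}

#' @export
print.cornea_geometry <- function(x, ...) {
  cat(sprintf("cornea geometry: posterior R %.2f mm, anterior R %.2f mm, thickness %.0f um, aperture %.1f mm\n",
              x$posterior_radius, x$anterior_radius, 1000 * x$thickness,
              x$aperture_radius))
  invisible(x)
}

#' Structured axisymmetric mesh of the cornea and holder
#'
#' Builds a mapped quadrilateral grid between the two concentric spherical
#' arcs, from the apex (on the symmetry axis) to the clamp aperture, and
#' continues the grid radially outward as a stiff elastic flange representing
#' the holder ring; the corneal periphery and the holder therefore share nodes
#' (bonded contact) and the outer edge of the flange is fully fixed.
#'
#' @param geom A [cornea_geometry()].
#' @param n_through_thickness Elements through the corneal thickness (>= 2).
#' @param n_meridian Elements along the meridian from apex to clamp (>= 20).
#' @param n_holder Elements along the holder flange.
#' @return Object of class `ap_mesh` with fields `nodes` (n x 2 matrix of
#'   (r, z) in mm), `elem` (nel x 4 counterclockwise connectivity), `mat_id`
#'   (1 = cornea, 2 = holder) and named node/edge `sets` (apex nodes, axis
#'   nodes, clamped nodes, anterior/posterior edge chains).
#' @export
build_mesh <- function(geom, n_through_thickness = 4L, n_meridian = 100L,
                       n_holder = 10L) {
  stopifnot(inherits(geom, "cornea_geometry"))
  if (n_through_thickness < 2L) stop("n_through_thickness must be >= 2", call. = FALSE)
  if (n_meridian < 20L) stop("n_meridian must be >= 20", call. = FALSE)
  nt <- as.integer(n_through_thickness)
  nm <- as.integer(n_meridian)
  nh <- as.integer(n_holder)

  Rp <- geom$posterior_radius
  t <- geom$thickness
  Rmid <- Rp + t / 2
  phi_ap <- asin(geom$aperture_radius / Rmid)
  dphi_h <- geom$holder_width / Rmid
  phi <- c(seq(0, phi_ap, length.out = nm + 1L),
           phi_ap + seq_len(nh) / nh * dphi_h)
  rho <- Rp + t * (0:nt) / nt

  ncol_j <- nm + nh + 1L
  nid <- function(i, j) j * (nt + 1L) + i + 1L # i in 0..nt, j in 0..nm+nh
  nodes <- matrix(0, (nt + 1L) * ncol_j, 2L)
  for (j in 0:(ncol_j - 1L)) {
    idx <- nid(0:nt, j)
    nodes[idx, 1L] <- rho * sin(phi[j + 1L])
    nodes[idx, 2L] <- rho * cos(phi[j + 1L])
  }
  nodes[nid(0:nt, 0L), 1L] <- 0 # exact axis

  nel <- nt * (nm + nh)
  elem <- matrix(0L, nel, 4L)
  mat_id <- integer(nel)
  e <- 0L
  for (j in 0:(nm + nh - 1L)) {
    for (i in 0:(nt - 1L)) {
      e <- e + 1L
      elem[e, ] <- c(nid(i, j), nid(i, j + 1L), nid(i + 1L, j + 1L), nid(i + 1L, j))
      mat_id[e] <- if (j < nm) 1L else 2L
    }
  }

  # edge chains, ordered apex -> clamp; node order chosen so that positive
  # pressure with the solver's normal convention acts inward on the anterior
  # surface (air puff) and outward on the posterior surface (IOP)
  ja <- 0:(nm + nh - 1L)
  anterior_edges <- cbind(nid(nt, ja), nid(nt, ja + 1L))
  jp <- 0:(nm - 1L)
  posterior_edges <- cbind(nid(0L, jp + 1L), nid(0L, jp))

  sets <- list(
    apex_anterior = nid(nt, 0L),
    apex_posterior = nid(0L, 0L),
    axis_nodes = nid(0:nt, 0L),
    clamped_nodes = nid(0:nt, nm + nh),
    anterior_nodes = nid(nt, 0:(nm + nh)),
    posterior_nodes = nid(0L, 0:nm),
    anterior_edges = anterior_edges,
    posterior_edges = posterior_edges,
    cornea_elems = which(mat_id == 1L),
    holder_elems = which(mat_id == 2L)
  )

  mesh <- structure(list(nodes = nodes, elem = elem, mat_id = mat_id,
                         sets = sets, geom = geom,
                         n_through_thickness = nt, n_meridian = nm,
                         n_holder = nh),
                    class = "ap_mesh")
  # fail fast on inverted elements
  invisible(fe_problem(nodes, elem, rep(1, nel), rep(0, nel), rep(200, nel)))
  mesh
}

#' @export
print.ap_mesh <- function(x, ...) {
  cat(sprintf("axisymmetric mesh: %d nodes, %d elements (%d cornea + %d holder), %d x %d corneal grid\n",
              nrow(x$nodes), nrow(x$elem), length(x$sets$cornea_elems),
              length(x$sets$holder_elems), x$n_through_thickness, x$n_meridian))
  invisible(x)
}

# cross-section area (in the r-z plane) of a set of elements, by the shoelace
# formula; used to check the mesh measure against the analytic annular cap
mesh_section_area <- function(mesh, which_elems = NULL) {
  el <- if (is.null(which_elems)) mesh$elem else mesh$elem[which_elems, , drop = FALSE]
  r <- matrix(mesh$nodes[el, 1L], nrow(el), 4L)
  z <- matrix(mesh$nodes[el, 2L], nrow(el), 4L)
  a <- 0.5 * abs((r[, 1] * z[, 2] - r[, 2] * z[, 1]) +
                 (r[, 2] * z[, 3] - r[, 3] * z[, 2]) +
                 (r[, 3] * z[, 4] - r[, 4] * z[, 3]) +
                 (r[, 4] * z[, 1] - r[, 1] * z[, 4]))
  sum(a)
}

# local wall thickness along the meridian: distance between posterior and
# anterior nodes of each column
mesh_wall_thickness <- function(mesh) {
  nt <- mesh$n_through_thickness
  jmax <- mesh$n_meridian
  sapply(0:jmax, function(j) {
    i0 <- j * (nt + 1L) + 1L
    i1 <- j * (nt + 1L) + nt + 1L
    sqrt(sum((mesh$nodes[i1, ] - mesh$nodes[i0, ])^2))
  })
}

#' Export a mesh in a plain-text unstructured-grid format
#'
#' Writes the mesh as a legacy ASCII VTK file (quad cells in the r-z plane)
#' for visualization in standard viewers.
#'
#' @param mesh An `ap_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  writeLines(c("# vtk DataFile Version 3.0", "axisymmetric cornea mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  nel <- nrow(mesh$elem)
  writeLines(sprintf("CELLS %d %d", nel, 5L * nel), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elem[, 1L] - 1L, mesh$elem[, 2L] - 1L,
                     mesh$elem[, 3L] - 1L, mesh$elem[, 4L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nel), con)
  writeLines(rep("9", nel), con)
  invisible(path)
}
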