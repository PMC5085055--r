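#' Phantom material and geometry presets
#'
#' Ships the three hydrogel contact-lens materials used as corneal phantoms
#' (short names G, S, Q), with Mooney-Rivlin constants chosen so that the
#' equivalent small-strain Young's modulus \eqn{6(C_{10}+C_{01})} equals the
#' manufacturer modulus (0.16, 0.30, 0.38 MPa respectively), split in the
#' fixed ratio \eqn{C_{10} = 3 C_{01}}; and the three thickness variants
#' (350, 450, 550 um) on a posterior radius of 8.60 mm with concentric
#' anterior surfaces (8.95, 9.05, 9.15 mm).
#'
#' @return A data frame with columns `material`, `modulus_mpa`, `c10`, `c01`.
#' @export
phantom_presets <- function() {
  E <- c(G = 0.16, S = 0.30, Q = 0.38)
  data.frame(material = names(E), modulus_mpa = unname(E),
             c10 = unname(E) / 8, c01 = unname(E) / 24,
             row.names = NULL)
}

#' @rdname phantom_presets
#' @param material One of `"G"`, `"S"`, `"Q"`.
#' @export
phantom_material <- function(material = c("G", "S", "Q")) {
  material <- match.arg(material)
  p <- phantom_presets()
  row <- p[p$material == material, ]
  mooney_rivlin(row$c10, row$c01)
}

#' @rdname phantom_presets
#' @param thickness_um Corneal thickness in micrometres (350, 450 or 550, or
#'   any positive value).
#' @export
phantom_geometry <- function(thickness_um = 550) {
  cornea_geometry(posterior_radius = 8.60, thickness = thickness_um / 1000)
}

#' Synthetic air-puff study with known ground truth
#'
#' Bundles everything needed to generate a Corvis-like synthetic measurement:
#' the ground-truth material, the cornea geometry, IOP, the air-pulse load and
#' the noise model. Displacement noise is i.i.d. Gaussian per sampled surface
#' point per frame, emulating sub-pixel segmentation error of the Scheimpflug
#' frames (default sigma 0.010 mm); stress noise for tensile curves is
#' multiplicative Gaussian (default 2% relative).
#'
#' @param truth [mooney_rivlin()] ground-truth parameters.
#' @param geom [cornea_geometry()].
#' @param iop IOP in mmHg.
#' @param load [airpuff_load()].
#' @param displacement_noise_sd Per-sample surface noise sigma, mm.
#' @param stress_noise_rel Relative stress noise sigma.
#' @param rng_seed Integer seed.
#' @return Object of class `synthetic_study`.
#' @export
synthetic_study <- function(truth = phantom_material("S"),
                            geom = phantom_geometry(450),
                            iop = 15, load = airpuff_load(),
                            displacement_noise_sd = 0.010,
                            stress_noise_rel = 0.02,
                            rng_seed = 1L) {
  stopifnot(displacement_noise_sd >= 0, stress_noise_rel >= 0)
  structure(list(truth = truth, geom = geom, iop = iop, load = load,
                 displacement_noise_sd = displacement_noise_sd,
                 stress_noise_rel = stress_noise_rel,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_study")
}

# run fn with a private, restored RNG stream seeded with `seed`
with_seed <- function(seed, fn) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Add measurement noise to a deformation record
#'
#' Perturbs every sampled surface height with i.i.d. Gaussian noise; the
#' first frame becomes the noisy reference (the instrument references
#' displacements to its own first image, so the apex trace starts exactly
#' at 0), and the apex trace is re-derived from the noisy surfaces. Like the
#' instrument's segmentation software, the apex value of each frame is
#' estimated sub-pixel by averaging the sampled surface over a small lateral
#' window (+/- 0.25 mm) around the axis; the window is identical for the
#' reference and every frame, so the surface-curvature contribution cancels
#' in the displacement and the noise on the apex trace is suppressed.
#'
#' @param record A noise-free `deformation_record` (full, not reduced).
#' @param sd Noise standard deviation, mm.
#' @param seed Integer seed.
#' @param apex_window Lateral half-width (mm) of the apex estimation window.
#' @return A noisy `deformation_record`.
#' @export
perturb_record <- function(record, sd, seed, apex_window = 0.25) {
  stopifnot(inherits(record, "deformation_record"), !record$reduced)
  if (sd == 0) return(record)
  with_seed(seed, function() {
    h <- record$heights +
      matrix(stats::rnorm(length(record$heights), 0, sd),
             nrow(record$heights), ncol(record$heights))
    ref <- h[1L, ]
    win <- which(abs(record$grid) <= apex_window)
    apex <- rowMeans(matrix(h[1L, win], nrow(h), length(win), byrow = TRUE) -
                     h[, win, drop = FALSE])
    new_deformation_record(times = record$times, grid = record$grid,
                           heights = h, reference = ref, apex_disp = apex,
                           reduced = FALSE,
                           meta = c(record$meta, list(noise_sd = sd, seed = seed)))
  })
}

#' Generate a synthetic air-puff measurement
#'
#' Forward-simulates the study's ground truth over the full frame sequence,
#' adds displacement noise, and (optionally) writes the measurement CSV files
#' plus a ground-truth JSON. Bitwise reproducible for a given study seed.
#'
#' @param study A [synthetic_study()].
#' @param dir Output directory, or `NULL` to skip writing files.
#' @param truth_record Optional precomputed noise-free record for this study
#'   (to amortize the forward simulation across replicate noise draws).
#' @param mesh Optional prebuilt mesh passed to [simulate_airpuff()].
#' @return List with `record` (noisy), `truth_record`, `truth` parameters and
#'   `paths` (NULL when `dir` is NULL).
#' @export
generate_airpuff_measurement <- function(study, dir = NULL,
                                         truth_record = NULL, mesh = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  if (is.null(truth_record)) {
    truth_record <- simulate_airpuff(study$geom, study$truth, iop = study$iop,
                                     load = study$load, frames = "all",
                                     mesh = mesh)
  }
  noisy <- perturb_record(truth_record, study$displacement_noise_sd,
                          study$rng_seed)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(spatial = file.path(dir, "spatial_profiles.csv"),
                  temporal = file.path(dir, "temporal_profile.csv"),
                  truth = file.path(dir, "ground_truth.json"))
    write_deformation_record(noisy, paths$spatial, paths$temporal)
    write_json_file(list(
      c10_mpa = study$truth$c10, c01_mpa = study$truth$c01,
      equivalent_modulus_mpa = small_strain_modulus(study$truth),
      thickness_mm = study$geom$thickness, iop_mmhg = study$iop,
      displacement_noise_sd_mm = study$displacement_noise_sd,
      rng_seed = study$rng_seed), paths$truth)
  }
  list(record = noisy, truth_record = truth_record, truth = study$truth,
       paths = paths)
}

#' Generate a synthetic uniaxial tensile measurement
#'
#' Evaluates the closed-form stress-strain curve of the ground-truth material
#' and adds multiplicative Gaussian stress noise; optionally writes the curve
#' CSV and ground-truth JSON. Reproducible per seed.
#'
#' @param params [mooney_rivlin()] ground truth.
#' @param spec A [tensile_spec()].
#' @param noise_rel Relative stress noise sigma.
#' @param seed Integer seed.
#' @param dir Output directory or `NULL`.
#' @return List with `curve` (noisy [stress_strain_curve()]), `truth_curve`
#'   and `paths`.
#' @export
generate_tensile_measurement <- function(params, spec = tensile_spec(),
                                         noise_rel = 0.02, seed = 1L,
                                         dir = NULL) {
  truth_curve <- simulate_tensile(params, spec)
  stress <- if (noise_rel > 0) {
    with_seed(seed, function() {
      truth_curve$stress * (1 + stats::rnorm(length(truth_curve$stress), 0, noise_rel))
    })
  } else {
    truth_curve$stress
  }
  curve <- stress_strain_curve(truth_curve$strain, stress)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(curve = file.path(dir, "stress_strain.csv"),
                  truth = file.path(dir, "tensile_truth.json"))
    write_stress_strain(curve, paths$curve)
    write_json_file(list(
      c10_mpa = params$c10, c01_mpa = params$c01,
      equivalent_modulus_mpa = small_strain_modulus(params),
      noise_rel = noise_rel, rng_seed = seed), paths$truth)
  }
  list(curve = curve, truth_curve = truth_curve, paths = paths)
}
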