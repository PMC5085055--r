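## Run configuration: one YAML/JSON document driving the CLI. All lengths in
## mm and pressures in MPa internally; the IOP is given in mmHg and converted
## explicitly (1 mmHg = 133.322 Pa).

config_schema <- list(
  geometry = c("posterior_radius", "thickness", "anterior_radius",
               "aperture_radius", "holder_youngs_modulus",
               "holder_poisson_ratio", "holder_width"),
  material = c("c10", "c01", "bulk_penalty"),
  iop_mmhg = NULL,
  airpuff = c("peak_pressure_mpa", "spatial_sigma_mm", "duration_ms",
              "n_frames", "footprint_csv"),
  solver = c("tol", "n_increments", "n_through_thickness", "n_meridian",
             "n_holder"),
  inverse = c("c10_bounds", "c01_bounds", "n_initial_samples",
              "max_fe_evaluations", "ga_population", "ga_generations",
              "merit_tolerance"),
  tensile = c("free_length", "width", "thickness", "max_strain", "n_points"),
  noise = c("displacement_sigma_mm", "stress_sigma_rel"),
  seed = NULL
)

config_error <- function(msg) {
  stop(structure(class = c("ap_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read and validate a run configuration
#'
#' Loads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration document and
#' validates it against the package's schema; unknown keys are rejected.
#' Missing sections fall back to package defaults.
#'
#' @param path Configuration file.
#' @return A validated configuration list of class `run_config` with
#'   constructed `geometry`, `material` (if given), `load`, `inverse`,
#'   `tensile` objects plus `iop_mmhg`, `solver`, `noise` and `seed` entries.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param raw A configuration list (as parsed from YAML/JSON).
#' @export
as_run_config <- function(raw) {
  if (!is.list(raw)) config_error("configuration must be a mapping")
  unknown <- setdiff(names(raw), names(config_schema))
  if (length(unknown)) {
    config_error(paste("unknown configuration keys:", paste(unknown, collapse = ", ")))
  }
  for (sec in names(raw)) {
    allowed <- config_schema[[sec]]
    if (!is.null(allowed) && is.list(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), allowed)
      if (length(bad)) {
        config_error(sprintf("unknown keys in '%s': %s", sec,
                             paste(bad, collapse = ", ")))
      }
    }
  }
  gsec <- raw$geometry
  geom <- tryCatch({
    args <- list(
      posterior_radius = gsec$posterior_radius %||% 8.60,
      thickness = gsec$thickness %||% 0.55,
      aperture_radius = gsec$aperture_radius %||% 5.5,
      holder_material = linear_elastic(gsec$holder_youngs_modulus %||% 1500,
                                       gsec$holder_poisson_ratio %||% 0.3),
      holder_width = gsec$holder_width %||% 2)
    if (!is.null(gsec$anterior_radius)) args$anterior_radius <- gsec$anterior_radius
    do.call(cornea_geometry, args)
  }, ap_config_error = function(e) config_error(conditionMessage(e)),
     error = function(e) config_error(conditionMessage(e)))

  material <- NULL
  if (!is.null(raw$material)) {
    material <- tryCatch(
      mooney_rivlin(raw$material$c10, raw$material$c01, raw$material$bulk_penalty),
      error = function(e) config_error(conditionMessage(e)))
  }

  asec <- raw$airpuff
  footprint <- NULL
  if (!is.null(asec$footprint_csv)) {
    if (!file.exists(asec$footprint_csv)) {
      config_error(sprintf("footprint table not found: %s", asec$footprint_csv))
    }
    footprint <- as.matrix(utils::read.csv(asec$footprint_csv))
  }
  load <- tryCatch(
    airpuff_load(peak_pressure = asec$peak_pressure_mpa %||% 0.0045,
                 spatial_sigma = asec$spatial_sigma_mm %||% 1.5,
                 duration = asec$duration_ms %||% 30,
                 n_frames = asec$n_frames %||% 140L,
                 footprint = footprint),
    error = function(e) config_error(conditionMessage(e)))

  isec <- raw$inverse
  inv <- tryCatch(
    inverse_config(
      c10_bounds = unlist(isec$c10_bounds) %||% c(0.005, 2.0),
      c01_bounds = unlist(isec$c01_bounds) %||% c(0.005, 2.0),
      n_initial_samples = isec$n_initial_samples %||% 20L,
      max_fe_evaluations = isec$max_fe_evaluations %||% 80L,
      ga_population = isec$ga_population %||% 40L,
      ga_generations = isec$ga_generations %||% 50L,
      merit_tolerance = isec$merit_tolerance %||% 0.005,
      rng_seed = raw$seed %||% 1L),
    error = function(e) config_error(conditionMessage(e)))

  tsec <- raw$tensile
  tens <- tryCatch(
    tensile_spec(free_length = tsec$free_length %||% 12,
                 width = tsec$width %||% 3,
                 thickness = tsec$thickness %||% 0.55,
                 max_strain = tsec$max_strain %||% 0.4,
                 n_points = tsec$n_points %||% 81L),
    error = function(e) config_error(conditionMessage(e)))

  ssec <- raw$solver
  solver <- list(tol = ssec$tol %||% 1e-6,
                 n_increments = ssec$n_increments %||% 5L,
                 n_through_thickness = ssec$n_through_thickness %||% 4L,
                 n_meridian = ssec$n_meridian %||% 100L,
                 n_holder = ssec$n_holder %||% 10L)

  nsec <- raw$noise
  noise <- list(displacement_sigma_mm = nsec$displacement_sigma_mm %||% 0.010,
                stress_sigma_rel = nsec$stress_sigma_rel %||% 0.02)

  structure(list(geometry = geom, material = material,
                 iop_mmhg = raw$iop_mmhg %||% 15,
                 load = load, inverse = inv, tensile = tens,
                 solver = solver, noise = noise,
                 seed = as.integer(raw$seed %||% 1L)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
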