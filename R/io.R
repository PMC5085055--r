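## CSV dialects for deformation records and stress-strain curves.
##
## Full spatial file: header "x_mm,height_mm", then one block per frame, each
## preceded by a marker line "# frame <i> t=<ms>". Temporal file: header
## "t_ms,apex_disp_mm". The reduced form (what a Corvis-type instrument
## exports) is a single-block spatial file with columns
## "x_mm,height_ref_mm,height_hc_mm" plus the same temporal file.

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a deformation record to the package's CSV dialect
#'
#' @param record A `deformation_record`.
#' @param spatial_path Path for the spatial-profile CSV.
#' @param temporal_path Path for the temporal (apex displacement) CSV.
#' @param reduced Write the reduced two-column-profile form (reference + HC
#'   profile only) instead of all frames.
#' @return Invisibly, the two paths.
#' @export
write_deformation_record <- function(record, spatial_path, temporal_path,
                                     reduced = FALSE) {
  stopifnot(inherits(record, "deformation_record"))
  con <- file(spatial_path, "w")
  if (reduced || record$reduced) {
    hc <- which.max(record$apex_disp)
    hc_prof <- if (record$reduced) record$hc_profile else record$heights[hc, ]
    writeLines("x_mm,height_ref_mm,height_hc_mm", con)
    writeLines(paste(fmt_num(record$grid), fmt_num(record$reference),
                     fmt_num(hc_prof), sep = ","), con)
  } else {
    writeLines("x_mm,height_mm", con)
    for (k in seq_along(record$times)) {
      writeLines(sprintf("# frame %d t=%s", k, fmt_num(record$times[k])), con)
      writeLines(paste(fmt_num(record$grid), fmt_num(record$heights[k, ]),
                       sep = ","), con)
    }
  }
  close(con)
  con <- file(temporal_path, "w")
  writeLines("t_ms,apex_disp_mm", con)
  writeLines(paste(fmt_num(record$times), fmt_num(record$apex_disp), sep = ","), con)
  close(con)
  invisible(c(spatial_path, temporal_path))
}

parse_error <- function(path, line, msg) {
  stop(structure(class = c("ap_parse_error", "error", "condition"),
                 list(message = sprintf("%s:%d: %s", path, line, msg),
                      call = NULL)))
}

#' Read a deformation record
#'
#' Parses the package's spatial + temporal CSV dialect, accepting both the
#' full per-frame form and the reduced "reference + highest-concavity profile"
#' form. Malformed headers, ragged rows or non-monotone time columns raise a
#' parse error carrying the file and line number.
#'
#' @param spatial_path,temporal_path The two CSV files.
#' @return A `deformation_record`; reduced records have `reduced = TRUE` and
#'   carry only the reference and HC profiles (see [record_frame()]).
#' @export
read_deformation_record <- function(spatial_path, temporal_path) {
  tl <- readLines(temporal_path)
  if (length(tl) < 3L || tl[1L] != "t_ms,apex_disp_mm") {
    parse_error(temporal_path, 1L, "expected header 't_ms,apex_disp_mm'")
  }
  tm <- parse_csv_block(tl[-1L], 2L, temporal_path, offset = 1L)
  times <- tm[, 1L]
  if (any(diff(times) <= 0)) {
    parse_error(temporal_path, 1L + which(diff(times) <= 0)[1L] + 1L,
                "time column must be strictly increasing")
  }
  apex_disp <- tm[, 2L]

  sl <- readLines(spatial_path)
  if (length(sl) < 2L) parse_error(spatial_path, 1L, "empty spatial file")
  header <- sl[1L]
  if (header == "x_mm,height_ref_mm,height_hc_mm") {
    m <- parse_csv_block(sl[-1L], 3L, spatial_path, offset = 1L)
    grid <- m[, 1L]
    if (any(diff(grid) <= 0)) parse_error(spatial_path, 2L, "x_mm must be increasing")
    rec <- new_deformation_record(times = times, grid = grid, heights = NULL,
                                  reference = m[, 2L], apex_disp = apex_disp,
                                  reduced = TRUE)
    rec$hc_profile <- m[, 3L]
    return(rec)
  }
  if (header != "x_mm,height_mm") {
    parse_error(spatial_path, 1L, "expected header 'x_mm,height_mm' or reduced form")
  }
  markers <- grep("^# frame ", sl)
  if (!length(markers)) parse_error(spatial_path, 2L, "no '# frame' block markers found")
  ft <- regmatches(sl[markers], regexec("^# frame ([0-9]+) t=([-0-9.eE+]+)$", sl[markers]))
  bad <- which(lengths(ft) != 3L)
  if (length(bad)) parse_error(spatial_path, markers[bad[1L]], "malformed frame marker")
  frame_times <- as.numeric(vapply(ft, `[`, "", 3L))
  if (any(diff(frame_times) <= 0)) {
    parse_error(spatial_path, markers[which(diff(frame_times) <= 0)[1L] + 1L],
                "frame times must be strictly increasing")
  }
  if (length(frame_times) != length(times) ||
      max(abs(frame_times - times)) > 1e-9) {
    parse_error(spatial_path, markers[1L],
                "frame times disagree with the temporal file")
  }
  bounds <- c(markers, length(sl) + 1L)
  grid <- NULL
  heights <- NULL
  for (k in seq_along(markers)) {
    rows <- sl[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    m <- parse_csv_block(rows, 2L, spatial_path, offset = bounds[k])
    if (is.null(grid)) {
      grid <- m[, 1L]
      if (any(diff(grid) <= 0)) {
        parse_error(spatial_path, bounds[k] + 1L, "x_mm must be increasing")
      }
      heights <- matrix(NA_real_, length(markers), length(grid))
    } else if (nrow(m) != length(grid) || max(abs(m[, 1L] - grid)) > 1e-12) {
      parse_error(spatial_path, bounds[k] + 1L,
                  "frame blocks must share the same lateral grid")
    }
    heights[k, ] <- m[, 2L]
  }
  new_deformation_record(times = times, grid = grid, heights = heights,
                         reference = heights[1L, ], apex_disp = apex_disp,
                         reduced = FALSE)
}

# parse `lines` as a numeric CSV with `ncol` columns; `offset` is the line
# number of the last line before `lines` in the file (for error reporting)
parse_csv_block <- function(lines, ncol, path, offset = 0L) {
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != ncol)
  if (length(bad)) {
    parse_error(path, offset + which(keep)[bad[1L]],
                sprintf("expected %d comma-separated values", ncol))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = ncol, byrow = TRUE)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(rowSums(m)))[1L]
    parse_error(path, offset + which(keep)[bad], "non-numeric value")
  }
  m
}

#' Extract one frame's spatial profile from a record
#'
#' @param record A `deformation_record`.
#' @param frame Frame index.
#' @return Data frame with columns `x_mm`, `height_mm`.
#' @export
record_frame <- function(record, frame) {
  stopifnot(inherits(record, "deformation_record"))
  if (record$reduced) {
    hc <- which.max(record$apex_disp)
    if (frame != hc) {
      stop(sprintf(paste0("reduced record carries only the highest-concavity ",
                          "profile (frame %d); per-frame profiles are not available"), hc),
           call. = FALSE)
    }
    return(data.frame(x_mm = record$grid, height_mm = record$hc_profile))
  }
  stopifnot(frame >= 1L, frame <= nrow(record$heights))
  data.frame(x_mm = record$grid, height_mm = record$heights[frame, ])
}

#' Spatial displacement profile at highest concavity
#'
#' @param record A `deformation_record`.
#' @return Data frame with columns `x_mm`, `displacement_mm` (positive into
#'   the eye).
#' @export
hc_displacement_profile <- function(record) {
  hc <- which.max(record$apex_disp)
  prof <- if (record$reduced) record$hc_profile else record$heights[hc, ]
  data.frame(x_mm = record$grid, displacement_mm = record$reference - prof)
}

#' Write / read a stress-strain curve CSV
#'
#' Columns `strain,stress_MPa`.
#' @param curve A [stress_strain_curve()].
#' @param path File path.
#' @return `path` invisibly (write); a [stress_strain_curve()] (read).
#' @export
write_stress_strain <- function(curve, path) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  writeLines(c("strain,stress_MPa",
               paste(fmt_num(curve$strain), fmt_num(curve$stress), sep = ",")),
             path)
  invisible(path)
}

#' @rdname write_stress_strain
#' @export
read_stress_strain <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 3L || ln[1L] != "strain,stress_MPa") {
    parse_error(path, 1L, "expected header 'strain,stress_MPa'")
  }
  m <- parse_csv_block(ln[-1L], 2L, path, offset = 1L)
  stress_strain_curve(m[, 1L], m[, 2L])
}

# JSON result writer at full precision (bit-reproducible for identical runs)
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
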