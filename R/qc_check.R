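#' Run the static or dynamic half of a QC check
#'
#' The static check isolates random reconstruction error: the calibration
#' object rests at the centre of the capture volume for about 5 s and each
#' geometry check is scored by its expanded uncertainty (SD of the error
#' series times the coverage factor `k`). The dynamic check exposes
#' systematic error: the object is swept through the capture volume for at
#' least 20 s and each check is scored by the RMSE of its error series.
#'
#' Frames on which any marker a check needs is invalid are dropped for that
#' check only; the dropped fraction is recorded and a warning raised when it
#' exceeds `max_dropped_fraction`.
#'
#' @param trial A `mocap_trial` covering the geometry's markers.
#' @param geometry An [object_geometry()].
#' @param k Coverage factor for the expanded uncertainty (default 3).
#' @param min_duration_s Protocol minimum trial duration; shorter trials
#'   still produce a result but add a protocol warning. Defaults: 5 s
#'   (static), 20 s (dynamic).
#' @param max_dropped_fraction Dropped-frame fraction above which a warning
#'   is raised (default 0.2).
#' @param degenerate_mm Angle degeneracy threshold, see [measure_angles()].
#' @return A `qc_check` object: list with `phase`, `summaries` (error summary
#'   tibble), `series` (the `qc_series`), `max_distance`, `max_angle`,
#'   `warnings`, `k`, `duration_s`.
#' @export
run_static_check <- function(trial, geometry, k = 3, min_duration_s = 5,
                             max_dropped_fraction = 0.2, degenerate_mm = 1) {
  series <- measure_geometry(trial, geometry, degenerate_mm)
  summaries <- expanded_uncertainty(series, k = k)
  finish_check("static", trial, series, summaries, min_duration_s,
               max_dropped_fraction, k = k)
}

#' @rdname run_static_check
#' @export
run_dynamic_check <- function(trial, geometry, min_duration_s = 20,
                              max_dropped_fraction = 0.2, degenerate_mm = 1) {
  series <- measure_geometry(trial, geometry, degenerate_mm)
  summaries <- rmse(series)
  finish_check("dynamic", trial, series, summaries, min_duration_s,
               max_dropped_fraction, k = NA_real_)
}

finish_check <- function(phase, trial, series, summaries, min_duration_s,
                         max_dropped_fraction, k) {
  warnings <- character()
  dur <- trial_duration(trial)
  if (dur < min_duration_s) {
    warnings <- c(warnings, sprintf(
      "%s trial lasts %.2f s, below the protocol minimum of %g s",
      phase, dur, min_duration_s))
  }
  dropped <- summaries[summaries$fraction_frames_dropped > max_dropped_fraction, ]
  for (i in seq_len(nrow(dropped))) {
    warnings <- c(warnings, sprintf(
      "check '%s': %.1f%% of frames dropped (limit %.0f%%)",
      dropped$check_id[i], 100 * dropped$fraction_frames_dropped[i],
      100 * max_dropped_fraction))
  }
  max_of <- function(type) {
    v <- summaries$value[summaries$check_type == type]
    if (length(v)) max(v) else NA_real_
  }
  structure(list(phase = phase, summaries = summaries, series = series,
                 max_distance = max_of("distance"), max_angle = max_of("angle"),
                 warnings = warnings, k = k, duration_s = dur),
            class = "qc_check")
}

#' @export
print.qc_check <- function(x, ...) {
  metric <- if (x$phase == "static") "expanded uncertainty" else "RMSE"
  cat(sprintf("<qc_check> %s trial (%.2f s): %s\n", x$phase, x$duration_s, metric))
  cat(sprintf("  max distance %s: %.3f mm; max angle %s: %.3f deg\n",
              metric, x$max_distance, metric, x$max_angle))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Fraction of the capture volume swept by a trial
#'
#' Grids the horizontal (x-y) plane of the capture volume into square cells
#' and reports the fraction of cells the object centroid visits. The
#' horizontal plane is used because a hand-held sweep cannot visit every
#' height everywhere; covering the floor plan is the operational reading of
#' "the full capture volume has been covered".
#'
#' @param trial A `mocap_trial`.
#' @param volume_bounds 3 x 2 numeric matrix, rows x/y/z, columns min/max, in
#'   millimetres.
#' @param cell_mm Cell edge length in mm (default 500).
#' @return Fraction in \[0, 1\].
#' @export
volume_coverage <- function(trial, volume_bounds, cell_mm = 500) {
  volume_bounds <- as.matrix(volume_bounds)
  stopifnot(all(dim(volume_bounds) == c(3, 2)))
  if (any(volume_bounds[, 2] <= volume_bounds[, 1])) {
    stop("volume_bounds must have max > min on every axis", call. = FALSE)
  }
  nx <- max(1L, ceiling((volume_bounds[1, 2] - volume_bounds[1, 1]) / cell_mm))
  ny <- max(1L, ceiling((volume_bounds[2, 2] - volume_bounds[2, 1]) / cell_mm))
  if (n_frames(trial) == 0) {
    warning("empty trial: coverage is 0")
    return(0)
  }
  arr <- trial_array(trial)
  pos <- arr$positions
  pos[, , 1][!arr$valid] <- NA
  pos[, , 2][!arr$valid] <- NA
  pos[, , 3][!arr$valid] <- NA
  centroid <- apply(pos, c(1, 3), mean, na.rm = TRUE)
  keep <- is.finite(centroid[, 1]) & is.finite(centroid[, 2])
  if (!any(keep)) {
    warning("no frames with a valid centroid: coverage is 0")
    return(0)
  }
  ix <- pmin(nx, pmax(1, 1 + floor((centroid[keep, 1] - volume_bounds[1, 1]) / cell_mm)))
  iy <- pmin(ny, pmax(1, 1 + floor((centroid[keep, 2] - volume_bounds[2, 1]) / cell_mm)))
  length(unique(ix + nx * (iy - 1))) / (nx * ny)
}

#' Default capture-volume bounds
#'
#' The 5 m x 4 m x 2 m capture volume used as the common target in
#' multicentric gait-laboratory deployments, centred on the origin in x/y
#' with the floor at z = 0.
#'
#' @return 3 x 2 matrix in millimetres (rows x/y/z, columns min/max).
#' @export
default_volume_bounds <- function() {
  matrix(c(-2500, 2500, -2000, 2000, 0, 2000), nrow = 3, byrow = TRUE,
         dimnames = list(c("x", "y", "z"), c("min", "max")))
}
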