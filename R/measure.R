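#' Per-frame reconstructed geometry series
#'
#' `measure_distances()` and `measure_angles()` compare the reconstructed
#' marker positions of a trial frame by frame against the nominal inter-marker
#' geometry, returning a tidy `qc_series` tibble with one row per check per
#' frame: `check_id`, `check_type`, `nominal`, `frame`, `time`, `measured`,
#' `valid` and `error` (= measured - nominal, i.e. reconstructed minus known;
#' `NA` where the frame is invalid for that check).
#'
#' A frame is invalid for a check when any marker the check references is
#' invalid on that frame, or (angles only) when a defining vector is shorter
#' than `degenerate_mm`, below which the direction is numerically meaningless.
#'
#' @param trial A `mocap_trial` in millimetres.
#' @param geometry An [object_geometry()], or a tibble of distance checks
#'   (`id`, `a`, `b`, `nominal_mm`) / angle checks for the respective
#'   function.
#' @param degenerate_mm Vector-length threshold below which an angle is
#'   undefined on a frame (default 1 mm).
#' @return A `qc_series` tibble.
#' @export
measure_distances <- function(trial, geometry) {
  checks <- if (inherits(geometry, "object_geometry")) {
    geometry$distance_checks
  } else {
    tibble::as_tibble(geometry)
  }
  have <- trial_markers(trial)
  n <- n_frames(trial)
  rate <- trial_rate(trial)
  out <- vector("list", nrow(checks))
  for (i in seq_len(nrow(checks))) {
    a <- checks$a[i]; b <- checks$b[i]
    missing <- setdiff(c(a, b), have)
    if (length(missing)) {
      stop("distance check '", checks$id[i], "' references marker(s) ",
           paste(missing, collapse = ", "), " absent from the trial",
           call. = FALSE)
    }
    pa <- marker_matrix(trial, a); pb <- marker_matrix(trial, b)
    ok <- marker_valid(trial, a) & marker_valid(trial, b)
    d <- sqrt(rowSums((pa - pb)^2))
    d[!ok] <- NA_real_
    out[[i]] <- tibble::tibble(
      check_id = checks$id[i], check_type = "distance",
      nominal = checks$nominal_mm[i],
      frame = seq_len(n), time = (seq_len(n) - 1) / rate,
      measured = d, valid = ok, error = d - checks$nominal_mm[i]
    )
  }
  as_qc_series(dplyr::bind_rows(out))
}

#' @rdname measure_distances
#' @export
measure_angles <- function(trial, geometry, degenerate_mm = 1) {
  checks <- if (inherits(geometry, "object_geometry")) {
    geometry$angle_checks
  } else {
    normalise_angle_checks(geometry, trial_markers(trial))
  }
  have <- trial_markers(trial)
  n <- n_frames(trial)
  rate <- trial_rate(trial)
  out <- vector("list", nrow(checks))
  for (i in seq_len(nrow(checks))) {
    row <- checks[i, ]
    labs <- if (!is.na(row$vertex)) c(row$a, row$vertex, row$c) else
      c(row$a1, row$a2, row$b1, row$b2)
    missing <- setdiff(labs, have)
    if (length(missing)) {
      stop("angle check '", row$id, "' references marker(s) ",
           paste(missing, collapse = ", "), " absent from the trial",
           call. = FALSE)
    }
    if (!is.na(row$vertex)) {
      u <- marker_matrix(trial, row$a) - marker_matrix(trial, row$vertex)
      v <- marker_matrix(trial, row$c) - marker_matrix(trial, row$vertex)
    } else {
      u <- marker_matrix(trial, row$a2) - marker_matrix(trial, row$a1)
      v <- marker_matrix(trial, row$b2) - marker_matrix(trial, row$b1)
    }
    ok <- Reduce(`&`, lapply(labs, function(l) marker_valid(trial, l)))
    lu <- sqrt(rowSums(u^2)); lv <- sqrt(rowSums(v^2))
    ok <- ok & !is.na(lu) & !is.na(lv) & lu >= degenerate_mm & lv >= degenerate_mm
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    ang <- atan2(sqrt(rowSums(cr^2)), rowSums(u * v)) * 180 / pi
    ang[!ok] <- NA_real_
    if (n > 0 && !any(ok)) {
      stop("angle check '", row$id,
           "' is undefined on every frame (degenerate or invalid markers)",
           call. = FALSE)
    }
    out[[i]] <- tibble::tibble(
      check_id = row$id, check_type = "angle", nominal = row$nominal_deg,
      frame = seq_len(n), time = (seq_len(n) - 1) / rate,
      measured = ang, valid = ok, error = ang - row$nominal_deg
    )
  }
  as_qc_series(dplyr::bind_rows(out))
}

#' @rdname measure_distances
#' @export
measure_geometry <- function(trial, geometry, degenerate_mm = 1) {
  stopifnot(inherits(geometry, "object_geometry"))
  parts <- list()
  if (nrow(geometry$distance_checks)) {
    parts <- c(parts, list(measure_distances(trial, geometry)))
  }
  if (nrow(geometry$angle_checks)) {
    parts <- c(parts, list(measure_angles(trial, geometry, degenerate_mm)))
  }
  if (!length(parts)) stop("geometry declares no checks", call. = FALSE)
  as_qc_series(dplyr::bind_rows(parts))
}

as_qc_series <- function(df) {
  class(df) <- unique(c("qc_series", class(tibble::tibble())))
  df
}
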