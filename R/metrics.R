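#' Expanded uncertainty of a static error series
#'
#' Quantifies the random error of marker reconstruction from a static trial:
#' the sample standard deviation (n - 1 denominator, metrological convention)
#' of each check's error series, multiplied by a coverage factor `k`. With
#' `k = 3` the interval mean +/- SD*k covers 99.7% of Gaussian random errors.
#' The SD is taken about the series mean, so a constant bias in the static
#' pose does not inflate the random-error estimate; the bias is reported
#' separately as `mean_error`.
#'
#' @param series A `qc_series` from [measure_distances()], [measure_angles()]
#'   or [measure_geometry()]; may hold several checks.
#' @param k Coverage factor (default 3).
#' @return An `error summary` tibble, one row per check: `check_id`,
#'   `check_type`, `metric`, `value` (mm or deg), `k`, `mean_error`,
#'   `n_frames_used`, `fraction_frames_dropped`.
#' @export
expanded_uncertainty <- function(series, k = 3) {
  stopifnot(is.numeric(k), k > 0)
  summarise_series(series, function(err, n_total, info) {
    if (length(err) < 2) {
      stop("insufficient static frames for check '", info$check_id,
           "': expanded uncertainty needs >= 2 valid frames, got ",
           length(err), call. = FALSE)
    }
    tibble::tibble(metric = "expanded_uncertainty",
                   value = stats::sd(err) * k, k = k,
                   mean_error = mean(err))
  })
}

#' Root-mean-square error of a dynamic error series
#'
#' Quantifies the systematic error exposed by sweeping the calibration object
#' through the capture volume: per check, the square root of the mean squared
#' difference between reconstructed and nominal geometry over the valid
#' frames of the trial.
#'
#' @inheritParams expanded_uncertainty
#' @return An error summary tibble (see [expanded_uncertainty()]), with
#'   `metric = "rmse"` and `k = NA`.
#' @export
rmse <- function(series) {
  summarise_series(series, function(err, n_total, info) {
    if (length(err) < 1) {
      stop("no valid frames for check '", info$check_id, "'", call. = FALSE)
    }
    tibble::tibble(metric = "rmse", value = sqrt(mean(err^2)), k = NA_real_,
                   mean_error = mean(err))
  })
}

summarise_series <- function(series, f) {
  stopifnot(all(c("check_id", "check_type", "error", "valid") %in% names(series)))
  ids <- unique(series$check_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- series[series$check_id == ids[i], ]
    err <- sub$error[sub$valid]
    n_total <- nrow(sub)
    res <- f(err, n_total, list(check_id = ids[i]))
    out[[i]] <- tibble::tibble(
      check_id = ids[i],
      check_type = sub$check_type[1],
      res,
      n_frames_used = length(err),
      fraction_frames_dropped = if (n_total > 0) 1 - length(err) / n_total else 0
    )
  }
  dplyr::bind_rows(out)
}
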