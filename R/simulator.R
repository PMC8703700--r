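#' Motion, noise and distortion models for simulated trials
#'
#' The simulator poses a rigid calibration object frame by frame, applies a
#' deterministic spatial distortion to the true marker positions, then adds
#' per-marker Gaussian reconstruction noise and random dropout. It emulates
#' the two QC recordings: a static trial resting at the centre of the
#' capture volume, and a hand-held dynamic sweep of the volume.
#'
#' @param kind Motion kind: `"static"` (constant pose at the volume centre),
#'   `"raster"` (serpentine sweep of the horizontal plane with a slow height
#'   oscillation, the pattern an operator walking the volume produces) or
#'   `"lissajous"` (smooth quasi-periodic path filling the volume).
#' @param duration_s Trial length in seconds (> 0).
#' @param rate_hz Sampling frequency in Hz (default 100, a common camera
#'   rate).
#' @param volume_bounds 3 x 2 bounds matrix in mm, see
#'   [default_volume_bounds()].
#' @param rot_amp_deg Amplitude of the orientation oscillation around each
#'   axis, degrees (default 30 for moving kinds, 0 for static).
#' @param rot_freq_hz Frequency of the orientation oscillation (default 0.2).
#' @param margin_mm Clearance kept between the object path and the volume
#'   walls, on top of the object radius (default 100).
#' @return A `motion_model` list.
#' @export
motion_model <- function(kind = c("static", "raster", "lissajous"),
                         duration_s, rate_hz = 100,
                         volume_bounds = default_volume_bounds(),
                         rot_amp_deg = NULL, rot_freq_hz = 0.2,
                         margin_mm = 100) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0, rate_hz > 0)
  volume_bounds <- as.matrix(volume_bounds)
  stopifnot(all(dim(volume_bounds) == c(3, 2)),
            all(volume_bounds[, 2] > volume_bounds[, 1]))
  if (is.null(rot_amp_deg)) rot_amp_deg <- if (kind == "static") 0 else 30
  structure(list(kind = kind, duration_s = duration_s, rate_hz = rate_hz,
                 volume_bounds = volume_bounds, rot_amp_deg = rot_amp_deg,
                 rot_freq_hz = rot_freq_hz, margin_mm = margin_mm),
            class = "motion_model")
}

#' @rdname motion_model
#' @param sigma_mm Per-axis SD of the iid Gaussian reconstruction noise added
#'   independently to every marker on every frame (mm, >= 0).
#' @param dropout_prob Probability that a marker is lost (invalid) on a
#'   frame, independently per marker per frame (in \[0, 1)).
#' @export
noise_model <- function(sigma_mm = 0, dropout_prob = 0) {
  stopifnot(sigma_mm >= 0, dropout_prob >= 0, dropout_prob < 1)
  structure(list(sigma_mm = sigma_mm, dropout_prob = dropout_prob),
            class = "noise_model")
}

#' @rdname motion_model
#' @param dist_kind Distortion kind: `"none"`, `"uniform_scale"` (similarity
#'   transform `x -> c + (1 + s) (x - c)` about the volume centre `c`),
#'   `"affine"` (`x -> A x + b`) or `"smooth_field"` (`x -> x + w(x)` with
#'   `w` a smooth quadratic vector polynomial of bounded amplitude — the
#'   spatially varying bias a slightly wrong camera calibration leaves
#'   behind).
#' @param s Scale offset for `uniform_scale` (e.g. 0.01 stretches all lengths
#'   by 1%).
#' @param A,b Affine map (3 x 3 matrix, length-3 offset in mm) for
#'   `"affine"`.
#' @param amplitude_mm Peak displacement of the `smooth_field` warp (mm).
#' @param field_coef Optional 3 x 9 coefficient matrix for the smooth field
#'   (rows = output axis, columns = the quadratic monomials); a fixed
#'   default is used when omitted.
#' @export
distortion_model <- function(dist_kind = c("none", "uniform_scale", "affine",
                                           "smooth_field"),
                             s = 0, A = diag(3), b = c(0, 0, 0),
                             amplitude_mm = 0, field_coef = NULL) {
  dist_kind <- match.arg(dist_kind)
  if (dist_kind == "affine") {
    A <- as.matrix(A)
    stopifnot(all(dim(A) == c(3, 3)), length(b) == 3)
  }
  if (dist_kind == "smooth_field") {
    stopifnot(amplitude_mm >= 0)
    if (is.null(field_coef)) {
      # fixed smooth pattern: one lobe per axis, mixing all three coordinates
      field_coef <- matrix(c(
        0.3, -0.2, 0.1, 0.5, -0.4, 0.2, 0.3, 0.1, -0.2,
        -0.1, 0.4, -0.3, 0.2, 0.5, -0.2, -0.3, 0.2, 0.1,
        0.2, -0.1, 0.3, -0.2, 0.1, 0.6, 0.1, -0.3, 0.2
      ), nrow = 3, byrow = TRUE)
    }
    field_coef <- as.matrix(field_coef)
    stopifnot(all(dim(field_coef) == c(3, 9)))
  }
  structure(list(kind = dist_kind, s = s, A = A, b = b,
                 amplitude_mm = amplitude_mm, field_coef = field_coef),
            class = "distortion_model")
}

#' Simulation configuration
#'
#' @param geometry An [object_geometry()] with `local_positions` for every
#'   marker.
#' @param motion A [motion_model()].
#' @param noise A [noise_model()].
#' @param distortion A [distortion_model()].
#' @param seed Integer random seed; the whole trial is deterministic given
#'   the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(geometry, motion, noise = noise_model(),
                       distortion = distortion_model(), seed = 1L) {
  stopifnot(inherits(geometry, "object_geometry"),
            inherits(motion, "motion_model"),
            inherits(noise, "noise_model"),
            inherits(distortion, "distortion_model"))
  if (is.null(geometry$local_positions) ||
      !all(geometry$markers %in% rownames(geometry$local_positions))) {
    stop("simulation needs local_positions for every marker", call. = FALSE)
  }
  structure(list(geometry = geometry, motion = motion, noise = noise,
                 distortion = distortion, seed = as.integer(seed)),
            class = "sim_config")
}

rotation_matrix <- function(rx, ry, rz) {
  # intrinsic z-y-x Euler rotation, angles in radians
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# centroid path through the volume, one row per frame
motion_path <- function(motion, n, object_radius) {
  vb <- motion$volume_bounds
  centre <- rowMeans(vb)
  half <- (vb[, 2] - vb[, 1]) / 2 - object_radius - motion$margin_mm
  if (any(half <= 0)) {
    stop("object (radius ", round(object_radius), " mm plus margin) is too ",
         "large for the capture volume", call. = FALSE)
  }
  t <- (seq_len(n) - 1) / motion$rate_hz
  path <- switch(
    motion$kind,
    static = matrix(rep(centre, each = n), n, 3),
    raster = {
      # serpentine: sweep x back and forth while y advances and returns
      n_strips <- 8
      u <- (t / max(t[n], 1e-9))  # 0..1 over the trial
      yphase <- u * n_strips
      strip <- floor(yphase)
      frac <- yphase - strip
      x <- centre[1] + half[1] * ifelse(strip %% 2 == 0, 2 * frac - 1, 1 - 2 * frac)
      y <- centre[2] + half[2] * (2 * ((strip + frac) / n_strips) - 1)
      z <- centre[3] + half[3] * 0.5 * sin(2 * pi * 0.5 * t)
      cbind(x, y, z)
    },
    lissajous = cbind(
      centre[1] + half[1] * sin(2 * pi * 0.11 * t),
      centre[2] + half[2] * sin(2 * pi * 0.17 * t + pi / 3),
      centre[3] + half[3] * sin(2 * pi * 0.07 * t + pi / 5)
    )
  )
  path
}

#' Apply a distortion model to 3D positions
#'
#' @param points Numeric n x 3 matrix of positions (mm).
#' @param model A [distortion_model()].
#' @param volume_bounds 3 x 2 bounds matrix used to centre and normalise the
#'   field (default [default_volume_bounds()]).
#' @return The distorted n x 3 matrix.
#' @export
apply_distortion <- function(points, model, volume_bounds = default_volume_bounds()) {
  stopifnot(inherits(model, "distortion_model"))
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3", call. = FALSE)
  centre <- rowMeans(as.matrix(volume_bounds))
  switch(model$kind,
         none = points,
         uniform_scale = {
           sweep(sweep(points, 2, centre) * (1 + model$s), 2, centre, `+`)
         },
         affine = {
           t(model$A %*% t(points)) + matrix(model$b, nrow(points), 3, byrow = TRUE)
         },
         smooth_field = {
           if (model$amplitude_mm == 0) return(points)
           half <- (volume_bounds[, 2] - volume_bounds[, 1]) / 2
           u <- sweep(sweep(points, 2, centre), 2, half, `/`)  # roughly [-1, 1]
           monomials <- cbind(u[, 1], u[, 2], u[, 3],
                              u[, 1] * u[, 2], u[, 2] * u[, 3], u[, 1] * u[, 3],
                              u[, 1]^2, u[, 2]^2, u[, 3]^2)
           w <- monomials %*% t(model$field_coef)
           # normalise so the worst-case per-axis displacement inside the
           # volume equals the stated amplitude
           denom <- max(rowSums(abs(model$field_coef)), 1e-12)
           points + w * (model$amplitude_mm / denom)
         })
}

#' Simulate a marker-trajectory trial
#'
#' Per frame: pose the rigid object along the motion path (rotation +
#' translation), distort the true marker positions with the configured
#' systematic field, add iid Gaussian noise, then apply dropout. Given the
#' same `sim_config` (including seed) the result is bit-identical.
#'
#' @param config A [sim_config()].
#' @return A `mocap_trial`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geom <- config$geometry
  motion <- config$motion
  local <- geom$local_positions[geom$markers, , drop = FALSE]
  local_c <- sweep(local, 2, colMeans(local))
  radius <- sqrt(max(rowSums(local_c^2)))
  n <- max(1L, round(motion$duration_s * motion$rate_hz))
  m <- nrow(local_c)
  path <- motion_path(motion, n, radius)
  withr::with_seed(config$seed, {
    t <- (seq_len(n) - 1) / motion$rate_hz
    amp <- motion$rot_amp_deg * pi / 180
    ph <- if (motion$kind == "static") c(0, 0, 0) else stats::runif(3, 0, 2 * pi)
    rx <- amp * sin(2 * pi * motion$rot_freq_hz * t + ph[1])
    ry <- amp * sin(2 * pi * motion$rot_freq_hz * 0.73 * t + ph[2])
    rz <- amp * sin(2 * pi * motion$rot_freq_hz * 1.31 * t + ph[3])
    pos <- array(NA_real_, c(n, m, 3))
    for (i in seq_len(n)) {
      R <- rotation_matrix(rx[i], ry[i], rz[i])
      true <- t(R %*% t(local_c)) +
        matrix(path[i, ], m, 3, byrow = TRUE)
      pos[i, , ] <- apply_distortion(true, config$distortion,
                                     motion$volume_bounds)
    }
    if (config$noise$sigma_mm > 0) {
      pos <- pos + array(stats::rnorm(n * m * 3, sd = config$noise$sigma_mm),
                         c(n, m, 3))
    }
    valid <- matrix(TRUE, n, m)
    if (config$noise$dropout_prob > 0) {
      valid <- matrix(stats::runif(n * m) >= config$noise$dropout_prob, n, m)
    }
    new_trial(pos, geom$markers, motion$rate_hz, valid = valid,
              kind = if (motion$kind == "static") "static" else "dynamic",
              source = sprintf("simulated(%s, seed=%d)", motion$kind,
                               config$seed))
  })
}

#' Parameter-recovery experiment
#'
#' Runs the full QC pipeline on a simulated static and dynamic trial pair
#' and tabulates the measured metrics next to the injected simulation
#' parameters and, where one exists, the analytic expectation: with iid
#' isotropic noise of SD `sigma` per axis on both markers, a distance-error
#' series has SD `sqrt(2) * sigma`, so its expanded uncertainty tends to
#' `k * sqrt(2) * sigma` and its dynamic RMSE to `sqrt(2) * sigma`; a
#' uniform scale offset `s` makes every distance RMSE `s * nominal` and
#' leaves angles untouched.
#'
#' @param config A [sim_config()]; its motion model is used for the dynamic
#'   trial, while the static trial reuses its duration/rate at the volume
#'   centre.
#' @param k Coverage factor for the static check.
#' @return Tibble with one row per check per phase: injected `sigma_mm` and
#'   `scale_s`, `metric`, `value` and `expected` (NA where no closed form is
#'   tabulated).
#' @export
recovery_experiment <- function(config, k = 3) {
  stopifnot(inherits(config, "sim_config"))
  geom <- config$geometry
  static_cfg <- config
  static_cfg$motion <- motion_model("static",
                                    duration_s = config$motion$duration_s,
                                    rate_hz = config$motion$rate_hz,
                                    volume_bounds = config$motion$volume_bounds)
  static_cfg$distortion <- distortion_model("none")
  dynamic_cfg <- config
  if (config$motion$kind == "static") {
    dynamic_cfg$motion <- motion_model("lissajous",
                                       duration_s = config$motion$duration_s,
                                       rate_hz = config$motion$rate_hz,
                                       volume_bounds = config$motion$volume_bounds)
  }
  dynamic_cfg$seed <- config$seed + 1L

  static <- run_static_check(simulate_trial(static_cfg), geom, k = k)
  dynamic <- run_dynamic_check(simulate_trial(dynamic_cfg), geom)

  sigma <- config$noise$sigma_mm
  s <- if (config$distortion$kind == "uniform_scale") config$distortion$s else NA_real_
  nominal_of <- function(ids) {
    tid <- tidy(geom)
    tid$nominal[match(ids, tid$check_id)]
  }
  stat <- dplyr::mutate(
    static$summaries,
    phase = "static", sigma_mm = sigma, scale_s = s,
    expected = ifelse(.data$check_type == "distance", k * sqrt(2) * sigma,
                      NA_real_))
  dyn <- dplyr::mutate(
    dynamic$summaries,
    phase = "dynamic", sigma_mm = sigma, scale_s = s,
    expected = dplyr::case_when(
      !is.na(s) & sigma == 0 & check_type == "distance" ~
        abs(s) * nominal_of(check_id),
      !is.na(s) & sigma == 0 & check_type == "angle" ~ 0,
      is.na(s) & check_type == "distance" ~ sqrt(2) * sigma,
      TRUE ~ NA_real_))
  dplyr::bind_rows(stat, dyn)[, c("phase", "check_id", "check_type", "metric",
                                  "sigma_mm", "scale_s", "value", "expected",
                                  "n_frames_used")]
}
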