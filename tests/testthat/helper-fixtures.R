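# Small geometries and trials built in code for the tests.

triangle_geometry <- function() {
  pos <- rbind(A = c(0, 0, 0), B = c(3, 0, 0), C = c(0, 4, 0))
  object_geometry(
    name = "triangle-345",
    markers = c("A", "B", "C"),
    local_positions = pos,
    distance_checks = tibble::tibble(
      id = c("ab", "bc"), a = c("A", "B"), b = c("B", "C"),
      nominal_mm = c(3, 5)),
    angle_checks = tibble::tibble(
      id = "bac", a = "B", vertex = "A", c = "C", nominal_deg = 90)
  )
}

# trial that places a rigid object at one fixed pose on every frame
static_object_trial <- function(local, n = 10, rate_hz = 100,
                                offset = c(0, 0, 0)) {
  m <- nrow(local)
  pos <- array(NA_real_, c(n, m, 3))
  for (i in seq_len(n)) {
    pos[i, , ] <- local + matrix(offset, m, 3, byrow = TRUE)
  }
  new_trial(pos, rownames(local), rate_hz)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# rigid object under an independent random rigid transform on every frame
random_rigid_trial <- function(local, n = 50, rate_hz = 100,
                               translation_scale = 1000) {
  m <- nrow(local)
  pos <- array(NA_real_, c(n, m, 3))
  for (i in seq_len(n)) {
    R <- random_rotation()
    tvec <- rnorm(3, sd = translation_scale)
    pos[i, , ] <- t(R %*% t(local)) + matrix(tvec, m, 3, byrow = TRUE)
  }
  new_trial(pos, rownames(local), rate_hz)
}

wand_sim <- function(kind, duration_s, sigma_mm = 0, dropout = 0,
                     distortion = distortion_model("none"), seed = 1,
                     rate_hz = 100, geometry = example_wand_geometry()) {
  sim_config(geometry,
             motion_model(kind, duration_s = duration_s, rate_hz = rate_hz),
             noise = noise_model(sigma_mm = sigma_mm, dropout_prob = dropout),
             distortion = distortion, seed = seed)
}
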