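test_that("simulation is deterministic given the seed", {
  cfg <- wand_sim("lissajous", 2, sigma_mm = 0.3, dropout = 0.05, seed = 99)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_trial(wand_sim("lissajous", 2, sigma_mm = 0.3, dropout = 0.05,
                                seed = 100))
  expect_false(identical(t1$x, t3$x))
})

test_that("a noiseless static simulation repeats one pose exactly", {
  tr <- simulate_trial(wand_sim("static", 1, seed = 4))
  df <- as.data.frame(tr)
  for (m in trial_markers(tr)) {
    sub <- df[df$marker == m, ]
    expect_equal(diff(range(sub$x)), 0)
    expect_equal(diff(range(sub$y)), 0)
    expect_equal(diff(range(sub$z)), 0)
  }
  # and the object sits at the centre of the volume
  vb <- default_volume_bounds()
  expect_equal(mean(df$z), mean(vb[3, ]), tolerance = 50)
})

test_that("the object path stays inside the capture volume", {
  for (kind in c("raster", "lissajous")) {
    tr <- simulate_trial(wand_sim(kind, 30, seed = 17))
    vb <- default_volume_bounds()
    expect_true(all(tr$x >= vb[1, 1] & tr$x <= vb[1, 2]))
    expect_true(all(tr$y >= vb[2, 1] & tr$y <= vb[2, 2]))
    expect_true(all(tr$z >= vb[3, 1] & tr$z <= vb[3, 2]))
  }
  # an object larger than the volume is refused
  big <- object_geometry("big", c("A", "B"),
                         local_positions = rbind(A = c(0, 0, 0),
                                                 B = c(9000, 0, 0)),
                         distance_checks = tibble::tibble(
                           id = "ab", a = "A", b = "B", nominal_mm = 9000))
  expect_error(simulate_trial(sim_config(big, motion_model("raster", 5))),
               "too large")
})

test_that("distortion maps do what they claim", {
  vb <- default_volume_bounds()
  centre <- rowMeans(vb)
  pts <- matrix(rnorm(30, sd = 400), 10, 3) +
    matrix(centre, 10, 3, byrow = TRUE)

  expect_equal(apply_distortion(pts, distortion_model("none"), vb), pts)

  # uniform scale: a point 100 mm from centre moves 1 mm radially at s=0.01
  p <- matrix(centre + c(100, 0, 0), 1, 3)
  got <- apply_distortion(p, distortion_model("uniform_scale", s = 0.01), vb)
  expect_equal(unname(got[1, ] - centre), c(101, 0, 0))

  # affine
  A <- diag(c(1.01, 1, 0.99)); b <- c(5, -3, 2)
  got_a <- apply_distortion(pts, distortion_model("affine", A = A, b = b), vb)
  expect_equal(got_a, t(A %*% t(pts)) + matrix(b, 10, 3, byrow = TRUE))

  # smooth field: identity at zero amplitude, bounded otherwise
  expect_equal(
    apply_distortion(pts, distortion_model("smooth_field", amplitude_mm = 0), vb),
    pts)
  warped <- apply_distortion(pts, distortion_model("smooth_field",
                                                   amplitude_mm = 2), vb)
  expect_true(all(abs(warped - pts) <= 2 + 1e-9))
  expect_gt(max(abs(warped - pts)), 0)
})

test_that("uniform scale stretches every measured distance by 1+s", {
  g <- example_wand_geometry()
  tr <- simulate_trial(wand_sim("lissajous", 5, seed = 3,
                                distortion = distortion_model("uniform_scale",
                                                              s = 0.005)))
  series <- measure_distances(tr, g)
  ratio <- series$measured / series$nominal
  expect_equal(range(ratio), c(1.005, 1.005), tolerance = 1e-9)
})

test_that("dropout produces the expected dropped-frame fraction", {
  p <- 0.1
  tr <- simulate_trial(wand_sim("lissajous", 100, dropout = p, seed = 14))
  g <- example_wand_geometry()
  s <- rmse(measure_distances(tr, g))
  # for a 2-marker check: P(dropped) = 1 - (1-p)^2
  expected <- 1 - (1 - p)^2
  expect_equal(mean(s$fraction_frames_dropped), expected, tolerance = 0.03)
})

test_that("recovery experiment tabulates injected vs measured vs expected", {
  cfg <- wand_sim("lissajous", 10, sigma_mm = 0.1, seed = 5)
  tab <- recovery_experiment(cfg)
  expect_setequal(unique(tab$phase), c("static", "dynamic"))
  stat_d <- tab[tab$phase == "static" & tab$check_type == "distance", ]
  expect_equal(unique(stat_d$expected), 3 * sqrt(2) * 0.1)
  expect_equal(stat_d$value, stat_d$expected, tolerance = 0.15)
  dyn_d <- tab[tab$phase == "dynamic" & tab$check_type == "distance", ]
  expect_equal(unique(dyn_d$expected), sqrt(2) * 0.1)
  expect_equal(dyn_d$value, dyn_d$expected, tolerance = 0.1)

  # scale-distortion recovery: expected RMSE is s * nominal, angles 0
  cfg2 <- wand_sim("raster", 10, seed = 6,
                   distortion = distortion_model("uniform_scale", s = 0.01))
  tab2 <- recovery_experiment(cfg2)
  dyn2 <- tab2[tab2$phase == "dynamic", ]
  d <- dyn2[dyn2$check_type == "distance", ]
  expect_equal(d$value, d$expected, tolerance = 1e-6)
  a <- dyn2[dyn2$check_type == "angle", ]
  expect_true(all(a$value < 1e-9))
})

test_that("distance RMSE grows strictly with the scale distortion", {
  g <- example_wand_geometry()
  rmse_at <- function(s) {
    tr <- simulate_trial(wand_sim("raster", 5, seed = 11,
                                  distortion = distortion_model("uniform_scale",
                                                                s = s)))
    run_dynamic_check(tr, g, min_duration_s = 0)$max_distance
  }
  vals <- vapply(c(0.001, 0.005, 0.01), rmse_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("invalid model parameters are rejected", {
  expect_error(noise_model(sigma_mm = -1))
  expect_error(noise_model(dropout_prob = 1))
  expect_error(motion_model("static", duration_s = 0))
  expect_error(distortion_model("nope"))
  g_nopos <- object_geometry("n", c("A", "B"),
                             distance_checks = tibble::tibble(
                               id = "ab", a = "A", b = "B", nominal_mm = 1))
  expect_error(sim_config(g_nopos, motion_model("static", 1)),
               "local_positions")
})
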