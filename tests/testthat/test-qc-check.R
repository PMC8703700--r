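test_that("noiseless trials give zero metrics; short trials warn", {
  g <- example_wand_geometry()
  st <- run_static_check(simulate_trial(wand_sim("static", 5, seed = 1)), g)
  expect_true(all(st$summaries$value == 0))
  expect_equal(st$max_distance, 0)
  expect_equal(st$max_angle, 0)
  expect_length(st$warnings, 0)

  # 3 s static with the 5 s protocol minimum: result plus warning
  short <- run_static_check(simulate_trial(wand_sim("static", 3, seed = 1)), g)
  expect_true(all(short$summaries$value == 0))
  expect_match(short$warnings, "below the protocol minimum", all = FALSE)

  dy <- run_dynamic_check(simulate_trial(wand_sim("lissajous", 21, seed = 2)), g)
  expect_lt(max(dy$summaries$value), 1e-9)
  expect_length(dy$warnings, 0)
  short_dy <- run_dynamic_check(
    simulate_trial(wand_sim("lissajous", 5, seed = 2)), g)
  expect_match(short_dy$warnings, "below the protocol minimum", all = FALSE)
})

test_that("per-frame rigid transforms leave all metrics at zero", {
  g <- triangle_geometry()
  local <- g$local_positions * 100  # 300/400/500 mm triangle
  g2 <- object_geometry("tri", g$markers, local_positions = local,
                        distance_checks = dplyr::mutate(g$distance_checks,
                                                        nominal_mm = nominal_mm * 100),
                        angle_checks = g$angle_checks)
  set.seed(5)
  tr <- random_rigid_trial(local, n = 100)
  st <- run_static_check(tr, g2, min_duration_s = 0)
  dy <- run_dynamic_check(tr, g2, min_duration_s = 0)
  expect_lt(max(st$summaries$value), 1e-9)
  expect_lt(max(dy$summaries$value), 1e-9)
})

test_that("garbage coordinates on invalid frames change nothing", {
  g <- example_wand_geometry()
  tr <- simulate_trial(wand_sim("lissajous", 5, sigma_mm = 0.2, seed = 6))
  ref <- run_dynamic_check(tr, g)

  arr <- spqc:::trial_array(tr)
  n <- dim(arr$positions)[1]
  valid <- arr$valid
  set.seed(7)
  kill <- sample(n, 40)
  valid[kill, 2] <- FALSE
  pos <- arr$positions
  pos[kill, 2, ] <- 1e12  # absurd garbage where the mask says invalid
  tr2 <- new_trial(pos, arr$labels, trial_rate(tr), valid = valid)
  got <- run_dynamic_check(tr2, g)

  # checks not involving W2 are bit-identical
  unaffected <- c("bar_long", "stem_seg")
  expect_equal(got$summaries$value[got$summaries$check_id %in% unaffected],
               ref$summaries$value[ref$summaries$check_id %in% unaffected])
  # affected checks use exactly the surviving frames and stay close
  ab <- got$summaries[got$summaries$check_id == "bar_left", ]
  expect_equal(ab$n_frames_used, n - 40)
  expect_equal(ab$value, ref$summaries$value[ref$summaries$check_id == "bar_left"],
               tolerance = 0.1)
})

test_that("excessive dropout raises a warning per check", {
  g <- example_wand_geometry()
  tr <- simulate_trial(wand_sim("lissajous", 5, sigma_mm = 0.1, dropout = 0.2,
                                seed = 8))
  dy <- run_dynamic_check(tr, g)
  expect_match(dy$warnings, "frames dropped", all = FALSE)
  # raising the allowance silences it
  dy2 <- run_dynamic_check(tr, g, max_dropped_fraction = 0.9)
  expect_false(any(grepl("frames dropped", dy2$warnings)))
})

test_that("volume coverage counts visited floor-plan cells", {
  vb <- matrix(c(0, 1000, 0, 1000, 0, 1000), 3, 2, byrow = TRUE)
  # 2x2 grid of 500 mm cells; centroid path visiting every cell
  centres <- rbind(c(250, 250, 500), c(750, 250, 500),
                   c(250, 750, 500), c(750, 750, 500))
  pos <- array(NA_real_, c(4, 1, 3))
  pos[, 1, ] <- centres
  tr <- new_trial(pos, "M", 10)
  expect_equal(volume_coverage(tr, vb, cell_mm = 500), 1)

  # static point in one cell
  tr1 <- new_trial(array(rep(c(250, 250, 500), each = 5), c(5, 1, 3)), "M", 10)
  expect_equal(volume_coverage(tr1, vb, cell_mm = 500), 0.25)

  # raster over half the plane
  xs <- seq(25, 975, by = 50)
  half <- expand.grid(x = xs, y = seq(25, 475, by = 50))
  pos2 <- array(NA_real_, c(nrow(half), 1, 3))
  pos2[, 1, 1] <- half$x; pos2[, 1, 2] <- half$y; pos2[, 1, 3] <- 500
  tr2 <- new_trial(pos2, "M", 10)
  expect_equal(volume_coverage(tr2, vb, cell_mm = 500), 0.5)

  # empty trial: zero with a warning
  tr0 <- new_trial(array(numeric(0), c(0, 1, 3)), "M", 10)
  expect_warning(cov0 <- volume_coverage(tr0, vb), "empty")
  expect_equal(cov0, 0)

  expect_error(volume_coverage(tr1, matrix(c(1, 0, 0, 1, 0, 1), 3, 2)), "max > min")
})

test_that("report maxima follow the highest-error reporting rule", {
  # synthetic summaries with known maxima
  g <- object_geometry(
    "rig", c("A", "B"),
    distance_checks = tibble::tibble(id = "ab", a = "A", b = "B", nominal_mm = 100))
  mk_check <- function(values, phase) {
    summaries <- tibble::tibble(
      check_id = paste0("d", seq_along(values)), check_type = "distance",
      metric = if (phase == "static") "expanded_uncertainty" else "rmse",
      value = values, k = if (phase == "static") 3 else NA_real_,
      mean_error = 0, n_frames_used = 100L, fraction_frames_dropped = 0)
    structure(list(phase = phase, summaries = summaries, series = NULL,
                   max_distance = max(values), max_angle = NA_real_,
                   warnings = character(), k = 3, duration_s = 30),
              class = "qc_check")
  }
  dyn <- mk_check(c(0.2, 0.5, 0.6, 0.8), "dynamic")
  rep_ <- build_report(dynamic = dyn)
  expect_equal(rep_$max_dynamic_distance, 0.8)
  expect_equal(rep_$pass_state, "report-only")

  # thresholds: 0.8 within a 2.5 mm bound passes, a 0.5 bound warns
  pass <- build_report(dynamic = dyn,
                       thresholds = list(max_dynamic_distance_mm = 2.5))
  expect_equal(pass$pass_state, "pass")
  warn <- build_report(dynamic = dyn,
                       thresholds = list(max_dynamic_distance_mm = 0.5))
  expect_equal(warn$pass_state, "warn")
  expect_match(warn$threshold_failures, "exceeds", all = FALSE)
  expect_error(build_report(dynamic = dyn, thresholds = list(nope = 1)),
               "unknown threshold")
  expect_error(build_report(), "at least one")
})

test_that("tidy() and glance() expose the report as tibbles", {
  g <- example_wand_geometry()
  st <- run_static_check(simulate_trial(wand_sim("static", 5, sigma_mm = 0.05,
                                                 seed = 3)), g)
  dy <- run_dynamic_check(simulate_trial(wand_sim("raster", 21, sigma_mm = 0.05,
                                                  seed = 4)), g)
  rep_ <- build_report(static = st, dynamic = dy, coverage = 0.9)
  td <- tidy(rep_)
  expect_equal(nrow(td), 16)
  expect_setequal(unique(td$phase), c("static", "dynamic"))
  expect_true(all(td$unit[td$check_type == "angle"] == "deg"))
  gl <- glance(rep_)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$max_static_distance,
               max(st$summaries$value[st$summaries$check_type == "distance"]))
  expect_equal(gl$pass_state, "report-only")
})
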