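test_that("geometry configs parse, validate and reject bad references", {
  path <- system.file("extdata", "wand_co1.json", package = "spqc")
  g <- load_geometry(path)
  expect_s3_class(g, "object_geometry")
  expect_equal(nrow(g$distance_checks), 5)
  expect_equal(nrow(g$angle_checks), 3)

  # minimal 3-marker config written from scratch
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    name = "tri", markers = list("A", "B", "C"),
    distance_checks = list(list(id = "ab", a = "A", b = "B", nominal_mm = 100),
                           list(id = "bc", a = "B", b = "C", nominal_mm = 100)),
    angle_checks = list(list(id = "abc", a = "A", vertex = "B", c = "C",
                             nominal_deg = 90))
  ), tmp, auto_unbox = TRUE)
  g2 <- load_geometry(tmp)
  expect_equal(nrow(g2$distance_checks), 2)
  expect_equal(nrow(g2$angle_checks), 1)

  # unknown marker referenced by a check
  expect_error(
    object_geometry("bad", c("A", "B"),
                    distance_checks = tibble::tibble(id = "x", a = "A", b = "M9",
                                                     nominal_mm = 10)),
    "M9")
  # non-positive nominal
  expect_error(
    object_geometry("bad", c("A", "B"),
                    distance_checks = tibble::tibble(id = "x", a = "A", b = "B",
                                                     nominal_mm = 0)),
    "non-positive")
  # self-distance
  expect_error(
    object_geometry("bad", c("A", "B"),
                    distance_checks = tibble::tibble(id = "x", a = "A", b = "A",
                                                     nominal_mm = 10)),
    "same marker")
})

test_that("declared nominals are checked against local positions", {
  pos <- rbind(A = c(0, 0, 0), B = c(100, 0, 0))
  ok <- object_geometry("g", c("A", "B"), local_positions = pos,
                        distance_checks = tibble::tibble(
                          id = "ab", a = "A", b = "B", nominal_mm = 100))
  expect_s3_class(ok, "object_geometry")
  # 2 mm off is beyond the 0.5 mm default manufacturing tolerance
  expect_error(
    object_geometry("g", c("A", "B"), local_positions = pos,
                    distance_checks = tibble::tibble(
                      id = "ab", a = "A", b = "B", nominal_mm = 102)),
    "manufacturing tolerance")
  # but fine with a wider declared tolerance
  wide <- object_geometry("g", c("A", "B"), local_positions = pos,
                          distance_checks = tibble::tibble(
                            id = "ab", a = "A", b = "B", nominal_mm = 102),
                          tolerance_mm = 5)
  expect_s3_class(wide, "object_geometry")
})

test_that("checks derived from positions reproduce textbook geometry", {
  side <- 100
  eq <- rbind(A = c(0, 0, 0), B = c(side, 0, 0),
              C = c(side / 2, side * sqrt(3) / 2, 0))
  g <- object_geometry("eq", c("A", "B", "C"), local_positions = eq)
  g <- derive_checks_from_positions(
    g,
    pairs = list(c("A", "B"), c("B", "C"), c("A", "C")),
    triplets = list(c("B", "A", "C"), c("A", "B", "C"), c("A", "C", "B")))
  expect_equal(g$distance_checks$nominal_mm, rep(side, 3))
  expect_equal(g$angle_checks$nominal_deg, rep(60, 3), tolerance = 1e-12)

  # collinear markers give a 180 degree vertex angle
  col <- rbind(A = c(0, 0, 0), B = c(1, 0, 0), C = c(2, 0, 0))
  gc <- derive_checks_from_positions(
    object_geometry("col", c("A", "B", "C"), local_positions = col),
    triplets = list(c("A", "B", "C")))
  expect_equal(gc$angle_checks$nominal_deg, 180)

  # 3-4-5 triangle hypotenuse
  tri <- rbind(A = c(0, 0, 0), B = c(3, 0, 0), C = c(0, 4, 0))
  gt <- derive_checks_from_positions(
    object_geometry("tri", c("A", "B", "C"), local_positions = tri),
    pairs = list(c("B", "C")))
  expect_equal(gt$distance_checks$nominal_mm, 5)

  # label without a local position
  expect_error(
    derive_checks_from_positions(
      object_geometry("tri", c("A", "B", "C", "D"), local_positions = tri),
      pairs = list(c("A", "D"))),
    "D")
})

test_that("derived nominals are invariant under rigid motion of the frame", {
  set.seed(11)
  base <- rbind(A = c(0, 0, 0), B = c(120, 0, 0), C = c(40, 80, 0),
                D = c(10, 20, 60))
  ref <- derive_checks_from_positions(
    object_geometry("obj", rownames(base), local_positions = base),
    pairs = list(c("A", "B"), c("C", "D")),
    triplets = list(c("A", "C", "D"), c("B", "A", "C")))
  for (rep_i in 1:5) {
    qr_ <- qr(matrix(rnorm(9), 3)); R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    moved <- t(R %*% t(base)) +
      matrix(rnorm(3, sd = 500), nrow(base), 3, byrow = TRUE)
    rownames(moved) <- rownames(base)
    got <- derive_checks_from_positions(
      object_geometry("obj", rownames(base), local_positions = moved),
      pairs = list(c("A", "B"), c("C", "D")),
      triplets = list(c("A", "C", "D"), c("B", "A", "C")))
    expect_equal(got$distance_checks$nominal_mm, ref$distance_checks$nominal_mm,
                 tolerance = 1e-9)
    expect_equal(got$angle_checks$nominal_deg, ref$angle_checks$nominal_deg,
                 tolerance = 1e-9)
    expect_true(all(got$angle_checks$nominal_deg >= 0 &
                      got$angle_checks$nominal_deg <= 180))
  }
})

test_that("geometry round-trips through its config file", {
  g <- example_wand_geometry(three_d = TRUE)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_geometry(g, tmp)
  g2 <- load_geometry(tmp)
  expect_equal(g2$name, g$name)
  expect_equal(g2$markers, g$markers)
  expect_equal(as.data.frame(g2$distance_checks), as.data.frame(g$distance_checks))
  expect_equal(as.data.frame(g2$angle_checks), as.data.frame(g$angle_checks))
  expect_equal(unname(g2$local_positions), unname(g$local_positions))
  expect_equal(rownames(g2$local_positions), rownames(g$local_positions))
})

test_that("vector-pair angles sharing an endpoint normalise to vertex form", {
  g <- object_geometry(
    "v", c("A", "B", "C"),
    angle_checks = tibble::tibble(id = "shared", a1 = "B", a2 = "A",
                                  b1 = "B", b2 = "C", nominal_deg = 45))
  row <- g$angle_checks[1, ]
  expect_equal(row$vertex, "B")
  expect_equal(row$a, "A")
  expect_equal(row$c, "C")
  expect_true(is.na(row$a1))
})

test_that("tidy() lists every declared check with units", {
  td <- tidy(example_wand_geometry())
  expect_equal(nrow(td), 8)
  expect_setequal(unique(td$unit), c("mm", "deg"))
})
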