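#' Declarative geometry of a calibration object
#'
#' An `object_geometry` describes the rigid calibration object a QC check is
#' scored against: its marker labels, optionally their coordinates in an
#' object-fixed frame, and the set of nominal inter-marker distances (mm) and
#' angles (degrees) the motion-capture reconstruction is compared with.
#'
#' Angle checks come in two forms. The vertex form names three markers
#' `(a, vertex, c)` and measures the angle between the rays `vertex -> a` and
#' `vertex -> c`. The vector-pair form names four markers `(a1, a2, b1, b2)`
#' and measures the angle between the vectors `a1 -> a2` and `b1 -> b2`. A
#' vector pair that shares an endpoint is normalised to the equivalent vertex
#' form. All angles are degrees in (0, 180].
#'
#' @param name Object name (free text).
#' @param markers Character vector of unique marker labels.
#' @param local_positions Optional numeric matrix (markers x 3, rownames =
#'   labels) of object-fixed coordinates in millimetres. When present, every
#'   declared nominal is cross-checked against the value recomputed from these
#'   coordinates within `tolerance_mm` / `tolerance_deg` (manufacturing
#'   tolerance).
#' @param distance_checks Tibble or data frame with columns `id`, `a`, `b`,
#'   `nominal_mm`.
#' @param angle_checks Tibble or data frame with columns `id`, `nominal_deg`
#'   and either `a`, `vertex`, `c` (vertex form) or `a1`, `a2`, `b1`, `b2`
#'   (vector-pair form). The two forms may be mixed across rows; unused cells
#'   are `NA`.
#' @param tolerance_mm,tolerance_deg Manufacturing tolerance used for the
#'   consistency check between declared nominals and `local_positions`.
#'   Defaults 0.5 mm and 0.5 degrees.
#'
#' @return An `object_geometry` object.
#' @export
object_geometry <- function(name,
                            markers,
                            local_positions = NULL,
                            distance_checks = NULL,
                            angle_checks = NULL,
                            tolerance_mm = 0.5,
                            tolerance_deg = 0.5) {
  stopifnot(is.character(markers), length(markers) >= 1)
  if (anyDuplicated(markers)) {
    stop("marker labels must be unique: duplicated ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(local_positions)) {
    local_positions <- as.matrix(local_positions)
    if (ncol(local_positions) != 3 || is.null(rownames(local_positions))) {
      stop("local_positions must be a labelled n x 3 matrix (mm)", call. = FALSE)
    }
    missing <- setdiff(rownames(local_positions), markers)
    if (length(missing)) {
      stop("local_positions has labels not in markers: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  dist <- normalise_distance_checks(distance_checks, markers)
  ang <- normalise_angle_checks(angle_checks, markers)

  geom <- structure(
    list(
      name = as.character(name),
      markers = markers,
      local_positions = local_positions,
      distance_checks = dist,
      angle_checks = ang,
      tolerance_mm = tolerance_mm,
      tolerance_deg = tolerance_deg
    ),
    class = "object_geometry"
  )
  check_geometry_consistency(geom)
  geom
}

normalise_distance_checks <- function(checks, markers) {
  if (is.null(checks) || nrow(as.data.frame(checks)) == 0) {
    return(tibble::tibble(id = character(), a = character(), b = character(),
                          nominal_mm = double()))
  }
  checks <- tibble::as_tibble(checks)
  need <- c("id", "a", "b", "nominal_mm")
  if (!all(need %in% names(checks))) {
    stop("distance checks need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  checks <- checks[need]
  for (i in seq_len(nrow(checks))) {
    row <- checks[i, ]
    for (lab in c(row$a, row$b)) {
      if (!lab %in% markers) {
        stop("distance check '", row$id, "' references marker '", lab,
             "' absent from the marker list", call. = FALSE)
      }
    }
    if (row$a == row$b) {
      stop("distance check '", row$id, "' uses the same marker twice",
           call. = FALSE)
    }
    if (!is.finite(row$nominal_mm) || row$nominal_mm <= 0) {
      stop("distance check '", row$id, "' has non-positive nominal_mm",
           call. = FALSE)
    }
  }
  if (anyDuplicated(checks$id)) stop("duplicate check ids", call. = FALSE)
  checks
}

normalise_angle_checks <- function(checks, markers) {
  empty <- tibble::tibble(id = character(), a = character(), vertex = character(),
                          c = character(), a1 = character(), a2 = character(),
                          b1 = character(), b2 = character(), nominal_deg = double())
  if (is.null(checks) || nrow(as.data.frame(checks)) == 0) return(empty)
  checks <- tibble::as_tibble(checks)
  for (col in c("a", "vertex", "c", "a1", "a2", "b1", "b2")) {
    if (!col %in% names(checks)) checks[[col]] <- NA_character_
  }
  if (!all(c("id", "nominal_deg") %in% names(checks))) {
    stop("angle checks need columns id and nominal_deg", call. = FALSE)
  }
  checks <- checks[names(empty)]
  out <- vector("list", nrow(checks))
  for (i in seq_len(nrow(checks))) {
    row <- checks[i, ]
    vertex_form <- !is.na(row$vertex)
    if (vertex_form) {
      labs <- c(row$a, row$vertex, row$c)
      if (anyNA(labs)) {
        stop("angle check '", row$id, "': vertex form needs a, vertex, c",
             call. = FALSE)
      }
      if (anyDuplicated(labs)) {
        stop("angle check '", row$id, "' repeats a marker label", call. = FALSE)
      }
    } else {
      labs <- c(row$a1, row$a2, row$b1, row$b2)
      if (anyNA(labs)) {
        stop("angle check '", row$id,
             "': give either {a, vertex, c} or {a1, a2, b1, b2}", call. = FALSE)
      }
      if (row$a1 == row$a2 || row$b1 == row$b2) {
        stop("angle check '", row$id, "' has a zero-length defining vector",
             call. = FALSE)
      }
      # a vector pair sharing an endpoint is canonically a vertex angle
      if (row$a1 == row$b1) {
        row$vertex <- row$a1; row$a <- row$a2; row$c <- row$b2
        row$a1 <- row$a2 <- row$b1 <- row$b2 <- NA_character_
      }
    }
    for (lab in labs) {
      if (!lab %in% markers) {
        stop("angle check '", row$id, "' references marker '", lab,
             "' absent from the marker list", call. = FALSE)
      }
    }
    if (!is.finite(row$nominal_deg) || row$nominal_deg <= 0 ||
        row$nominal_deg > 180) {
      stop("angle check '", row$id, "' needs nominal_deg in (0, 180]",
           call. = FALSE)
    }
    out[[i]] <- row
  }
  res <- dplyr::bind_rows(out)
  if (anyDuplicated(res$id)) stop("duplicate check ids", call. = FALSE)
  res
}

#' @export
print.object_geometry <- function(x, ...) {
  cat("<object_geometry> ", x$name, "\n", sep = "")
  cat("  markers: ", paste(x$markers, collapse = ", "), "\n", sep = "")
  cat("  distance checks: ", nrow(x$distance_checks),
      ", angle checks: ", nrow(x$angle_checks), "\n", sep = "")
  if (!is.null(x$local_positions)) cat("  local positions: yes\n")
  invisible(x)
}

#' @method tidy object_geometry
#' @export
tidy.object_geometry <- function(x, ...) {
  d <- x$distance_checks
  a <- x$angle_checks
  dplyr::bind_rows(
    tibble::tibble(check_id = d$id, check_type = "distance", nominal = d$nominal_mm,
                   unit = "mm"),
    tibble::tibble(check_id = a$id, check_type = "angle", nominal = a$nominal_deg,
                   unit = "deg")
  )
}

# distance / angle between labelled rows of a positions matrix
position_distance <- function(pos, a, b) {
  sqrt(sum((pos[a, ] - pos[b, ])^2))
}

position_angle <- function(pos, row) {
  if (!is.na(row$vertex)) {
    u <- pos[row$a, ] - pos[row$vertex, ]
    v <- pos[row$c, ] - pos[row$vertex, ]
  } else {
    u <- pos[row$a2, ] - pos[row$a1, ]
    v <- pos[row$b2, ] - pos[row$b1, ]
  }
  angle_between_deg(u, v)
}

#' Angle between two 3-vectors in degrees
#'
#' Numerically stable via `atan2(||u x v||, u . v)`; result in \[0, 180\].
#' @param u,v Numeric length-3 vectors.
#' @return Angle in degrees.
#' @keywords internal
angle_between_deg <- function(u, v) {
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

check_geometry_consistency <- function(geom) {
  pos <- geom$local_positions
  if (is.null(pos)) return(invisible(geom))
  d <- geom$distance_checks
  for (i in seq_len(nrow(d))) {
    labs <- c(d$a[i], d$b[i])
    if (!all(labs %in% rownames(pos))) next
    got <- position_distance(pos, d$a[i], d$b[i])
    if (abs(got - d$nominal_mm[i]) > geom$tolerance_mm) {
      stop("distance check '", d$id[i], "': declared nominal ", d$nominal_mm[i],
           " mm disagrees with local_positions (", signif(got, 6),
           " mm) beyond the ", geom$tolerance_mm, " mm manufacturing tolerance",
           call. = FALSE)
    }
  }
  a <- geom$angle_checks
  for (i in seq_len(nrow(a))) {
    row <- a[i, ]
    labs <- if (!is.na(row$vertex)) c(row$a, row$vertex, row$c) else
      c(row$a1, row$a2, row$b1, row$b2)
    if (!all(labs %in% rownames(pos))) next
    got <- position_angle(pos, row)
    if (abs(got - row$nominal_deg) > geom$tolerance_deg) {
      stop("angle check '", row$id, "': declared nominal ", row$nominal_deg,
           " deg disagrees with local_positions (", signif(got, 6),
           " deg) beyond the ", geom$tolerance_deg, " deg tolerance",
           call. = FALSE)
    }
  }
  invisible(geom)
}

#' Load an object geometry from a JSON config
#'
#' The config is a JSON object with fields `name`, `markers` (array of
#' labels), optional `local_positions` (map label -> \[x, y, z\] in mm),
#' `distance_checks` (array of `{id, a, b, nominal_mm}`) and `angle_checks`
#' (array of `{id, a, vertex, c, nominal_deg}` or
#' `{id, a1, a2, b1, b2, nominal_deg}`), plus optional `tolerance_mm` /
#' `tolerance_deg`.
#'
#' @param path Path to the JSON config file.
#' @return A validated [object_geometry()].
#' @export
load_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry config not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  geometry_from_config(cfg)
}

geometry_from_config <- function(cfg) {
  if (is.null(cfg$name) || is.null(cfg$markers)) {
    stop("geometry config needs 'name' and 'markers'", call. = FALSE)
  }
  markers <- vapply(cfg$markers, as.character, character(1))
  pos <- NULL
  if (!is.null(cfg$local_positions) && length(cfg$local_positions)) {
    pos <- do.call(rbind, lapply(cfg$local_positions, function(p) {
      p <- unlist(p)
      if (length(p) != 3) stop("local_positions entries must be [x, y, z]",
                               call. = FALSE)
      as.numeric(p)
    }))
    rownames(pos) <- names(cfg$local_positions)
  }
  rows_to_tbl <- function(lst) {
    if (is.null(lst) || !length(lst)) return(NULL)
    dplyr::bind_rows(lapply(lst, function(x) tibble::as_tibble(x)))
  }
  object_geometry(
    name = cfg$name,
    markers = markers,
    local_positions = pos,
    distance_checks = rows_to_tbl(cfg$distance_checks),
    angle_checks = rows_to_tbl(cfg$angle_checks),
    tolerance_mm = cfg$tolerance_mm %||% 0.5,
    tolerance_deg = cfg$tolerance_deg %||% 0.5
  )
}

#' Write an object geometry back to a JSON config
#'
#' `load_geometry(write_geometry(g, path))` reproduces `g`.
#'
#' @param geometry An [object_geometry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "object_geometry"))
  drop_na_cells <- function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, ])
      row[!vapply(row, function(v) is.na(v), logical(1))]
    })
  }
  cfg <- list(
    name = geometry$name,
    markers = as.list(geometry$markers),
    distance_checks = drop_na_cells(geometry$distance_checks),
    angle_checks = drop_na_cells(geometry$angle_checks),
    tolerance_mm = geometry$tolerance_mm,
    tolerance_deg = geometry$tolerance_deg
  )
  if (!is.null(geometry$local_positions)) {
    cfg$local_positions <- stats::setNames(
      lapply(seq_len(nrow(geometry$local_positions)),
             function(i) as.numeric(geometry$local_positions[i, ])),
      rownames(geometry$local_positions)
    )
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Derive nominal checks from object-fixed marker coordinates
#'
#' Augments a geometry with distance and/or vertex-angle checks whose nominal
#' values are computed from `local_positions` — the route used when a
#' calibration object's construction geometry is known (for example extra
#' markers fitted at manufactured positions) but the vendor sheet does not
#' list every pairwise value.
#'
#' @param geometry An [object_geometry()] with `local_positions`.
#' @param pairs List of 2-element character vectors `(a, b)`; each adds a
#'   distance check with nominal `|a - b|`.
#' @param triplets List of 3-element character vectors `(a, vertex, c)`; each
#'   adds a vertex-angle check with the angle computed at `vertex`.
#' @return The augmented `object_geometry`.
#' @export
derive_checks_from_positions <- function(geometry, pairs = list(),
                                         triplets = list()) {
  stopifnot(inherits(geometry, "object_geometry"))
  pos <- geometry$local_positions
  if (is.null(pos)) stop("geometry has no local_positions", call. = FALSE)
  need <- unique(unlist(c(pairs, triplets)))
  missing <- setdiff(need, rownames(pos))
  if (length(missing)) {
    stop("no local position for marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dist_new <- dplyr::bind_rows(lapply(pairs, function(p) {
    tibble::tibble(id = paste0("d_", p[1], "_", p[2]), a = p[1], b = p[2],
                   nominal_mm = position_distance(pos, p[1], p[2]))
  }))
  ang_new <- dplyr::bind_rows(lapply(triplets, function(tr) {
    row <- tibble::tibble(a = tr[1], vertex = tr[2], c = tr[3])
    tibble::tibble(id = paste0("a_", tr[1], "_", tr[2], "_", tr[3]),
                   a = tr[1], vertex = tr[2], c = tr[3],
                   nominal_deg = position_angle(pos, row))
  }))
  object_geometry(
    name = geometry$name,
    markers = geometry$markers,
    local_positions = pos,
    distance_checks = dplyr::bind_rows(geometry$distance_checks, dist_new),
    angle_checks = dplyr::bind_rows(geometry$angle_checks, ang_new),
    tolerance_mm = geometry$tolerance_mm,
    tolerance_deg = geometry$tolerance_deg
  )
}

#' Example T-wand calibration geometry
#'
#' A five-marker T-shaped wand resembling the calibration objects shipped with
#' optical motion-capture systems: three markers along a 240 mm cross bar and
#' two down a perpendicular 240 mm stem. The nominal dimensions are
#' illustrative placeholders, not any manufacturer's values — real QC runs
#' must declare the manufacturer-supplied geometry in their own config.
#'
#' @param three_d If `TRUE`, adds a rigidly attached three-marker triangle out
#'   of the wand plane (a calibration object with a third dimension in the
#'   marker configuration).
#' @return An [object_geometry()] with `local_positions`.
#' @export
example_wand_geometry <- function(three_d = FALSE) {
  pos <- rbind(
    W1 = c(0, 0, 0),
    W2 = c(160, 0, 0),
    W3 = c(240, 0, 0),
    W4 = c(160, -100, 0),
    W5 = c(160, -240, 0)
  )
  dist <- tibble::tibble(
    id = c("bar_long", "bar_short", "bar_left", "stem_full", "stem_seg"),
    a = c("W1", "W2", "W1", "W2", "W4"),
    b = c("W3", "W3", "W2", "W5", "W5"),
    nominal_mm = c(240, 80, 160, 240, 140)
  )
  ang <- tibble::tibble(
    id = c("bar_stem_left", "bar_stem_right", "bar_vs_stem"),
    a = c("W1", "W3", NA),
    vertex = c("W2", "W2", NA),
    c = c("W5", "W4", NA),
    a1 = c(NA, NA, "W1"), a2 = c(NA, NA, "W3"),
    b1 = c(NA, NA, "W2"), b2 = c(NA, NA, "W5"),
    nominal_deg = c(90, 90, 90)
  )
  if (three_d) {
    pos <- rbind(pos,
                 P1 = c(80, -40, 60),
                 P2 = c(200, -40, 60),
                 P3 = c(140, -40, 140))
    dist <- dplyr::bind_rows(dist, tibble::tibble(
      id = c("tri_base", "tri_left", "tri_right"),
      a = c("P1", "P1", "P2"), b = c("P2", "P3", "P3"),
      nominal_mm = c(120, 100, 100)
    ))
  }
  object_geometry(
    name = if (three_d) "example-wand-3d" else "example-wand",
    markers = rownames(pos),
    local_positions = pos,
    distance_checks = dist,
    angle_checks = ang
  )
}
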