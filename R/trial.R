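#' Marker-trajectory trials
#'
#' A trial is a tidy tibble of reconstructed 3D marker positions with class
#' `mocap_trial`: one row per frame per marker, columns `frame`, `time` (s),
#' `marker`, `x`, `y`, `z` (always millimetres) and `valid`. Points the
#' capture system failed to reconstruct carry `valid = FALSE` and `NA`
#' coordinates. Sampling rate, provenance and trial kind travel as attributes
#' (`rate_hz`, `source`, `kind`).
#'
#' @param positions Numeric array `frames x markers x 3` in millimetres.
#' @param labels Character vector of marker labels (length = dim 2).
#' @param rate_hz Sampling frequency in Hz (> 0).
#' @param valid Optional logical matrix `frames x markers`; defaults to
#'   finite coordinates.
#' @param kind One of `"static"`, `"dynamic"`, `"unknown"`.
#' @param source Free-text provenance (file path, simulator description).
#' @return A `mocap_trial` tibble.
#' @export
new_trial <- function(positions, labels, rate_hz, valid = NULL,
                      kind = "unknown", source = "in-memory") {
  stopifnot(is.numeric(rate_hz), rate_hz > 0)
  kind <- match.arg(kind, c("static", "dynamic", "unknown"))
  if (length(dim(positions)) != 3 || dim(positions)[3] != 3) {
    stop("positions must be a frames x markers x 3 array", call. = FALSE)
  }
  n_frames <- dim(positions)[1]
  n_markers <- dim(positions)[2]
  if (length(labels) != n_markers) {
    stop("labels length does not match positions", call. = FALSE)
  }
  if (is.null(valid)) {
    valid <- apply(is.finite(positions), c(1, 2), all)
    dim(valid) <- c(n_frames, n_markers)
  }
  stopifnot(is.logical(valid), all(dim(valid) == c(n_frames, n_markers)))
  pos <- positions
  for (k in 1:3) pos[, , k][!valid] <- NA_real_
  if (any(!is.finite(pos[, , 1][valid])) || any(!is.finite(pos[, , 2][valid])) ||
      any(!is.finite(pos[, , 3][valid]))) {
    stop("positions must be finite wherever valid", call. = FALSE)
  }
  tbl <- tibble::tibble(
    frame = rep(seq_len(n_frames), times = n_markers),
    time = (rep(seq_len(n_frames), times = n_markers) - 1) / rate_hz,
    marker = rep(labels, each = n_frames),
    x = as.vector(pos[, , 1]),
    y = as.vector(pos[, , 2]),
    z = as.vector(pos[, , 3]),
    valid = as.vector(valid)
  )
  structure(tbl,
            class = c("mocap_trial", class(tibble::tibble())),
            rate_hz = as.numeric(rate_hz),
            markers = labels,
            kind = kind,
            source = source)
}

#' Coerce a tidy data frame to a trial
#'
#' @param df Data frame with columns `frame`, `marker`, `x`, `y`, `z` and
#'   optionally `valid`. Missing frame/marker combinations and `NA`
#'   coordinates become invalid points.
#' @param rate_hz Sampling frequency (Hz).
#' @inheritParams new_trial
#' @return A `mocap_trial`.
#' @export
as_trial <- function(df, rate_hz, kind = "unknown", source = "data.frame") {
  need <- c("frame", "marker", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  labels <- unique(df$marker)
  frames <- seq_len(max(df$frame, 0L))
  n <- length(frames); m <- length(labels)
  pos <- array(NA_real_, c(n, m, 3))
  fi <- match(df$frame, frames)
  mi <- match(df$marker, labels)
  pos[cbind(fi, mi, 1)] <- df$x
  pos[cbind(fi, mi, 2)] <- df$y
  pos[cbind(fi, mi, 3)] <- df$z
  valid <- apply(is.finite(pos), c(1, 2), all)
  dim(valid) <- c(n, m)
  if ("valid" %in% names(df)) {
    vm <- matrix(FALSE, n, m)
    vm[cbind(fi, mi)] <- df$valid
    valid <- valid & vm
  }
  new_trial(pos, labels, rate_hz, valid = valid, kind = kind, source = source)
}

#' @rdname new_trial
#' @param trial A `mocap_trial`.
#' @export
trial_rate <- function(trial) attr(trial, "rate_hz")

#' @rdname new_trial
#' @export
trial_markers <- function(trial) attr(trial, "markers")

#' @rdname new_trial
#' @export
n_frames <- function(trial) {
  if (nrow(trial) == 0) return(0L)
  max(trial$frame)
}

#' @rdname new_trial
#' @export
trial_duration <- function(trial) n_frames(trial) / trial_rate(trial)

#' @export
print.mocap_trial <- function(x, ...) {
  cat(sprintf("<mocap_trial> %d frames x %d markers @ %g Hz (%.2f s, %s)\n",
              n_frames(x), length(trial_markers(x)), trial_rate(x),
              trial_duration(x), attr(x, "kind")))
  NextMethod()
}

# positions of one marker as an n x 3 matrix (NA where invalid)
marker_matrix <- function(trial, label) {
  rows <- trial[trial$marker == label, ]
  rows <- rows[order(rows$frame), ]
  cbind(rows$x, rows$y, rows$z)
}

marker_valid <- function(trial, label) {
  rows <- trial[trial$marker == label, ]
  rows$valid[order(rows$frame)]
}

# frames x markers x 3 array + valid matrix, markers in attr order
trial_array <- function(trial) {
  labels <- trial_markers(trial)
  n <- n_frames(trial)
  pos <- array(NA_real_, c(n, length(labels), 3))
  valid <- matrix(FALSE, n, length(labels))
  for (j in seq_along(labels)) {
    pos[, j, ] <- marker_matrix(trial, labels[j])
    valid[, j] <- marker_valid(trial, labels[j])
  }
  list(positions = pos, valid = valid, labels = labels)
}

#' Subset a trial to a set of markers
#'
#' Preserves frame count, sampling rate and validity mask; markers come out
#' in the requested order. Labels are matched exactly.
#'
#' @param trial A `mocap_trial`.
#' @param labels Marker labels to keep.
#' @return A `mocap_trial` with only the requested markers.
#' @export
select_markers <- function(trial, labels) {
  have <- trial_markers(trial)
  missing <- setdiff(labels, have)
  if (length(missing)) {
    stop("marker(s) not in trial: ", paste(missing, collapse = ", "),
         "; available: ", paste(have, collapse = ", "), call. = FALSE)
  }
  arr <- trial_array(trial)
  idx <- match(labels, arr$labels)
  new_trial(arr$positions[, idx, , drop = FALSE], labels, trial_rate(trial),
            valid = arr$valid[, idx, drop = FALSE],
            kind = attr(trial, "kind"), source = attr(trial, "source"))
}

#' Rename trial markers via a label map
#'
#' @param trial A `mocap_trial`.
#' @param label_map Named character vector or list, `old_label = "new_label"`.
#'   Labels not named in the map are kept unchanged.
#' @return The relabelled trial.
#' @export
rename_markers <- function(trial, label_map) {
  if (is.null(label_map) || !length(label_map)) return(trial)
  label_map <- unlist(label_map)
  old <- trial_markers(trial)
  unknown <- setdiff(names(label_map), old)
  if (length(unknown)) {
    stop("label_map names absent from trial: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  new <- ifelse(old %in% names(label_map), label_map[old], old)
  if (anyDuplicated(new)) stop("label_map produces duplicate labels", call. = FALSE)
  trial$marker <- new[match(trial$marker, old)]
  attr(trial, "markers") <- unname(new)
  trial
}
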