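#' Read and write trials as plain CSV
#'
#' The CSV dialect is: an optional comment line `# rate_hz=<value>`, then a
#' header row `frame,<L>_x,<L>_y,<L>_z,...` with one coordinate triple per
#' marker, one row per frame. Blank cells mark a point invalid on that frame.
#' Coordinates are millimetres.
#'
#' @param path Path to the CSV file.
#' @param rate_hz Sampling rate, overriding any `# rate_hz=` line; required
#'   when the file has none.
#' @return A `mocap_trial`.
#' @export
read_trial_csv <- function(path, rate_hz = NULL) {
  if (!file.exists(path)) stop("CSV file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  rate_line <- grep("^#\\s*rate_hz\\s*=", lines, value = TRUE)
  if (is.null(rate_hz)) {
    if (!length(rate_line)) {
      stop("no '# rate_hz=' line in ", path, " and no rate_hz supplied",
           call. = FALSE)
    }
    rate_hz <- as.numeric(sub("^#\\s*rate_hz\\s*=\\s*", "", rate_line[1]))
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, colClasses = "numeric")
  if (!"frame" %in% names(df)) stop("CSV needs a 'frame' column", call. = FALSE)
  coord_cols <- setdiff(names(df), "frame")
  bad <- coord_cols[!grepl("_(x|y|z)$", coord_cols)]
  if (length(bad)) {
    stop("columns are not <label>_x/_y/_z triples: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  labels <- unique(sub("_(x|y|z)$", "", coord_cols))
  expected <- as.vector(t(outer(labels, c("_x", "_y", "_z"), paste0)))
  if (!setequal(coord_cols, expected) || length(coord_cols) != length(expected)) {
    stop("inconsistent coordinate columns: each marker needs exactly ",
         "<label>_x, <label>_y, <label>_z", call. = FALSE)
  }
  n <- nrow(df)
  pos <- array(NA_real_, c(n, length(labels), 3))
  for (j in seq_along(labels)) {
    for (k in 1:3) {
      pos[, j, k] <- df[[paste0(labels[j], c("_x", "_y", "_z")[k])]]
    }
  }
  new_trial(pos, labels, rate_hz, source = path)
}

#' @rdname read_trial_csv
#' @param trial A `mocap_trial`.
#' @return For `write_trial_csv()`: `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  arr <- trial_array(trial)
  n <- dim(arr$positions)[1]
  cols <- list(frame = seq_len(n))
  for (j in seq_along(arr$labels)) {
    for (k in 1:3) {
      v <- arr$positions[, j, k]
      v[!arr$valid[, j]] <- NA_real_
      cols[[paste0(arr$labels[j], c("_x", "_y", "_z")[k])]] <- v
    }
  }
  df <- as.data.frame(cols, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g", trial_rate(trial)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Write a trial to disk in c3d or CSV format
#'
#' Thin dispatcher over [write_c3d()] and [write_trial_csv()]; the matching
#' reader reproduces positions, validity mask and sampling rate.
#'
#' @param trial A `mocap_trial`.
#' @param path Output path.
#' @param format `"c3d"` or `"csv"`; default guessed from the file extension.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, format = c("auto", "c3d", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     "c3d" = "c3d", "csv" = "csv",
                     stop("cannot guess format from extension of ", path,
                          call. = FALSE))
  }
  switch(format,
         c3d = write_c3d(trial, path),
         csv = write_trial_csv(trial, path))
}

#' Read a trial from c3d or CSV
#'
#' @inheritParams write_trial
#' @param label_map Optional label renaming, see [read_c3d()].
#' @param rate_hz Fallback sampling rate for CSV files without a rate line.
#' @return A `mocap_trial`.
#' @export
read_trial <- function(path, format = c("auto", "c3d", "csv"),
                       label_map = NULL, rate_hz = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     "c3d" = "c3d", "csv" = "csv",
                     stop("cannot guess format from extension of ", path,
                          call. = FALSE))
  }
  trial <- switch(format,
                  c3d = read_c3d(path, label_map = label_map),
                  csv = rename_markers(read_trial_csv(path, rate_hz = rate_hz),
                                       label_map))
  trial
}
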