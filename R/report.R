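#' Assemble a QC report
#'
#' Combines the static and/or dynamic check results, session metadata and
#' optional pass/fail thresholds into a `qc_report`. Following the reporting
#' rule that per-check errors show no bias with distance or angle amplitude,
#' the headline numbers are the four maxima: highest static expanded
#' uncertainty and highest dynamic RMSE, for distances and for angles.
#'
#' No thresholds are built in — what counts as acceptable depends on the
#' downstream use of the data — so without `thresholds` the report is
#' "report-only". With thresholds, `pass_state` is `"pass"` when every
#' configured maximum is within its bound and `"warn"` otherwise.
#'
#' @param static,dynamic `qc_check` objects from [run_static_check()] /
#'   [run_dynamic_check()]; at least one must be given.
#' @param metadata Named list of session metadata (site, system, operator,
#'   date, ...); stored verbatim.
#' @param thresholds Optional named list with any of `max_static_distance_mm`,
#'   `max_static_angle_deg`, `max_dynamic_distance_mm`,
#'   `max_dynamic_angle_deg`.
#' @param coverage Optional volume-coverage fraction from
#'   [volume_coverage()].
#' @param min_coverage Coverage fraction below which a protocol warning is
#'   added (used only when `coverage` is given; default 0.5).
#' @return A `qc_report` object.
#' @export
build_report <- function(static = NULL, dynamic = NULL, metadata = list(),
                         thresholds = NULL, coverage = NULL,
                         min_coverage = 0.5) {
  if (is.null(static) && is.null(dynamic)) {
    stop("need at least one of static / dynamic results", call. = FALSE)
  }
  for (x in list(static, dynamic)) {
    if (!is.null(x) && !inherits(x, "qc_check")) {
      stop("static/dynamic must be qc_check objects", call. = FALSE)
    }
  }
  warnings <- c(if (!is.null(static)) static$warnings,
                if (!is.null(dynamic)) dynamic$warnings)
  if (!is.null(coverage) && coverage < min_coverage) {
    warnings <- c(warnings, sprintf(
      "capture-volume coverage %.0f%% below the configured %.0f%% minimum",
      100 * coverage, 100 * min_coverage))
  }
  maxima <- list(
    max_static_distance = if (!is.null(static)) static$max_distance else NA_real_,
    max_static_angle = if (!is.null(static)) static$max_angle else NA_real_,
    max_dynamic_distance = if (!is.null(dynamic)) dynamic$max_distance else NA_real_,
    max_dynamic_angle = if (!is.null(dynamic)) dynamic$max_angle else NA_real_
  )
  pass_state <- "report-only"
  failures <- character()
  if (!is.null(thresholds) && length(thresholds)) {
    bound_of <- c(max_static_distance = "max_static_distance_mm",
                  max_static_angle = "max_static_angle_deg",
                  max_dynamic_distance = "max_dynamic_distance_mm",
                  max_dynamic_angle = "max_dynamic_angle_deg")
    unknown <- setdiff(names(thresholds), bound_of)
    if (length(unknown)) {
      stop("unknown threshold name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (field in names(bound_of)) {
      bound <- thresholds[[bound_of[[field]]]]
      if (is.null(bound) || is.na(maxima[[field]])) next
      if (maxima[[field]] > bound) {
        failures <- c(failures, sprintf("%s %.3f exceeds threshold %.3f",
                                        field, maxima[[field]], bound))
      }
    }
    pass_state <- if (length(failures)) "warn" else "pass"
  }
  structure(list(
    metadata = metadata,
    k = if (!is.null(static)) static$k else NA_real_,
    static_summaries = if (!is.null(static)) static$summaries else NULL,
    dynamic_summaries = if (!is.null(dynamic)) dynamic$summaries else NULL,
    max_static_distance = maxima$max_static_distance,
    max_static_angle = maxima$max_static_angle,
    max_dynamic_distance = maxima$max_dynamic_distance,
    max_dynamic_angle = maxima$max_dynamic_angle,
    coverage = coverage,
    protocol_warnings = warnings,
    threshold_failures = failures,
    thresholds = thresholds,
    pass_state = pass_state
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> pass_state:", x$pass_state, "\n")
  fmt <- function(v, unit) if (is.na(v)) "n/a" else sprintf("%.1f %s", v, unit)
  cat("  static max:  ", fmt(x$max_static_distance, "mm"), "/",
      fmt(x$max_static_angle, "deg"), "\n")
  cat("  dynamic max: ", fmt(x$max_dynamic_distance, "mm"), "/",
      fmt(x$max_dynamic_angle, "deg"), "\n")
  if (length(x$protocol_warnings)) {
    cat("  warnings:\n")
    for (w in x$protocol_warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Tidy a QC report into one row per check
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return Tibble with columns `phase`, `check_id`, `check_type`, `metric`,
#'   `value`, `unit`, `k`, `mean_error`, `n_frames_used`,
#'   `fraction_frames_dropped`.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  add_phase <- function(df, phase) {
    if (is.null(df)) return(NULL)
    dplyr::mutate(df,
                  phase = phase,
                  unit = ifelse(.data$check_type == "distance", "mm", "deg"),
                  .before = 1)
  }
  dplyr::bind_rows(add_phase(x$static_summaries, "static"),
                   add_phase(x$dynamic_summaries, "dynamic"))
}

#' One-row summary of a QC report
#'
#' @inheritParams tidy.qc_report
#' @return One-row tibble with the four maxima, coverage, warning count and
#'   pass state.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    max_static_distance = x$max_static_distance,
    max_static_angle = x$max_static_angle,
    max_dynamic_distance = x$max_dynamic_distance,
    max_dynamic_angle = x$max_dynamic_angle,
    coverage = x$coverage %||% NA_real_,
    n_warnings = length(x$protocol_warnings),
    pass_state = x$pass_state
  )
}

report_to_list <- function(report) {
  summaries_to_list <- function(df) {
    if (is.null(df)) return(NULL)
    lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, ])
      row[vapply(row, is.na, logical(1))] <- NULL
      row
    })
  }
  list(
    schema = "spqc-report/1",
    metadata = report$metadata,
    k = report$k,
    static_summaries = summaries_to_list(report$static_summaries),
    dynamic_summaries = summaries_to_list(report$dynamic_summaries),
    maxima = list(
      max_static_distance_mm = report$max_static_distance,
      max_static_angle_deg = report$max_static_angle,
      max_dynamic_distance_mm = report$max_dynamic_distance,
      max_dynamic_angle_deg = report$max_dynamic_angle
    ),
    coverage = report$coverage,
    protocol_warnings = as.list(report$protocol_warnings),
    threshold_failures = as.list(report$threshold_failures),
    thresholds = report$thresholds,
    pass_state = report$pass_state
  )
}

summary_tbl_from_list <- function(lst) {
  if (is.null(lst) || !length(lst)) return(NULL)
  df <- dplyr::bind_rows(lapply(lst, tibble::as_tibble))
  for (col in c("k", "mean_error")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df[c("check_id", "check_type", "metric", "value", "k", "mean_error",
       "n_frames_used", "fraction_frames_dropped")]
}

#' Serialise / restore a QC report as JSON
#'
#' The JSON file keeps full numeric precision; `read_report_json()` restores
#' a `qc_report` equal (up to representation) to the one written.
#'
#' @param report A `qc_report`.
#' @param path JSON path.
#' @return `write_report_json()`: `path`, invisibly. `read_report_json()`:
#'   a `qc_report`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = I(17), na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(lst$schema, "spqc-report/1")) {
    stop("not an spqc report JSON: ", path, call. = FALSE)
  }
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  structure(list(
    metadata = lst$metadata,
    k = num_or_na(lst$k),
    static_summaries = summary_tbl_from_list(lst$static_summaries),
    dynamic_summaries = summary_tbl_from_list(lst$dynamic_summaries),
    max_static_distance = num_or_na(lst$maxima$max_static_distance_mm),
    max_static_angle = num_or_na(lst$maxima$max_static_angle_deg),
    max_dynamic_distance = num_or_na(lst$maxima$max_dynamic_distance_mm),
    max_dynamic_angle = num_or_na(lst$maxima$max_dynamic_angle_deg),
    coverage = if (is.null(lst$coverage)) NULL else as.numeric(lst$coverage),
    protocol_warnings = as.character(unlist(lst$protocol_warnings)),
    threshold_failures = as.character(unlist(lst$threshold_failures)),
    thresholds = lst$thresholds,
    pass_state = lst$pass_state
  ), class = "qc_report")
}
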