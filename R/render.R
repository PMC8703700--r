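#' Render a QC report as Markdown, HTML or JSON
#'
#' Display formats round millimetre and degree values to one decimal place —
#' the granularity at which QC results are read and compared — while the JSON
#' format keeps full precision and round-trips losslessly through
#' [read_report_json()].
#'
#' @param report A `qc_report`.
#' @param format `"markdown"`, `"html"` or `"json"`.
#' @return A single character string holding the rendered document.
#' @export
render_report <- function(report, format = c("markdown", "html", "json")) {
  stopifnot(inherits(report, "qc_report"))
  format <- match.arg(format)
  switch(format,
         markdown = render_report_md(report),
         html = render_report_html(report),
         json = {
           tmp <- tempfile(fileext = ".json")
           on.exit(unlink(tmp))
           write_report_json(report, tmp)
           paste(readLines(tmp), collapse = "\n")
         })
}

fmt1 <- function(v, unit = "") {
  suffix <- ifelse(nzchar(unit), paste0(" ", unit), "")
  ifelse(is.na(v), "n/a", sprintf("%.1f%s", v, suffix))
}

render_report_md <- function(report) {
  lines <- c("# Motion-capture QC report", "")
  meta <- report$metadata
  if (length(meta)) {
    lines <- c(lines, "## Session", "")
    for (nm in names(meta)) {
      lines <- c(lines, sprintf("- %s: %s", nm, as.character(meta[[nm]])))
    }
    lines <- c(lines, "")
  }
  summary_table <- function(df, metric_label) {
    unit <- ifelse(df$check_type == "distance", "mm", "deg")
    c(sprintf("| check | type | %s | frames used | dropped |", metric_label),
      "|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %d | %.0f%% |",
              df$check_id, df$check_type, fmt1(df$value, unit),
              as.integer(df$n_frames_used), 100 * df$fraction_frames_dropped))
  }
  if (!is.null(report$static_summaries)) {
    lines <- c(lines,
               sprintf("## Static trial - expanded uncertainty (k = %g)", report$k),
               "",
               summary_table(report$static_summaries, "expanded uncertainty"),
               "")
  }
  if (!is.null(report$dynamic_summaries)) {
    lines <- c(lines, "## Dynamic trial - RMSE", "",
               summary_table(report$dynamic_summaries, "RMSE"), "")
  }
  lines <- c(lines, "## Highest errors", "",
             sprintf("- max static distance expanded uncertainty: %s",
                     fmt1(report$max_static_distance, "mm")),
             sprintf("- max static angle expanded uncertainty: %s",
                     fmt1(report$max_static_angle, "deg")),
             sprintf("- max dynamic distance RMSE: %s",
                     fmt1(report$max_dynamic_distance, "mm")),
             sprintf("- max dynamic angle RMSE: %s",
                     fmt1(report$max_dynamic_angle, "deg")),
             "")
  if (!is.null(report$coverage)) {
    lines <- c(lines, sprintf("- capture-volume coverage: %.0f%%",
                              100 * report$coverage), "")
  }
  lines <- c(lines, "## Warnings", "")
  if (length(report$protocol_warnings)) {
    lines <- c(lines, paste("-", report$protocol_warnings))
  } else {
    lines <- c(lines, "- none")
  }
  if (!identical(report$pass_state, "report-only")) {
    lines <- c(lines, "", sprintf("## Result: %s", toupper(report$pass_state)))
    if (length(report$threshold_failures)) {
      lines <- c(lines, "", paste("-", report$threshold_failures))
    }
  } else {
    lines <- c(lines, "", "## Result: report-only (no thresholds configured)")
  }
  paste(lines, collapse = "\n")
}

render_report_html <- function(report) {
  md <- strsplit(render_report_md(report), "\n")[[1]]
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  out <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
           "<title>Motion-capture QC report</title></head><body>")
  in_list <- FALSE
  close_list <- function() {
    if (in_list) { out <<- c(out, "</ul>"); in_list <<- FALSE }
  }
  i <- 1
  while (i <= length(md)) {
    line <- md[i]
    if (grepl("^# ", line)) {
      close_list(); out <- c(out, paste0("<h1>", esc(sub("^# ", "", line)), "</h1>"))
    } else if (grepl("^## ", line)) {
      close_list(); out <- c(out, paste0("<h2>", esc(sub("^## ", "", line)), "</h2>"))
    } else if (grepl("^\\| ", line)) {
      close_list()
      rows <- character()
      header <- TRUE
      while (i <= length(md) && grepl("^\\|", md[i])) {
        if (!grepl("^\\|---", md[i])) {
          cells <- strsplit(gsub("^\\||\\|$", "", md[i]), "\\|")[[1]]
          tag <- if (header) "th" else "td"
          rows <- c(rows, paste0("<tr>", paste0("<", tag, ">",
                                                esc(trimws(cells)),
                                                "</", tag, ">", collapse = ""),
                                 "</tr>"))
          header <- FALSE
        }
        i <- i + 1
      }
      out <- c(out, "<table>", rows, "</table>")
      next
    } else if (grepl("^- ", line)) {
      if (!in_list) { out <- c(out, "<ul>"); in_list <- TRUE }
      out <- c(out, paste0("<li>", esc(sub("^- ", "", line)), "</li>"))
    } else if (nzchar(trimws(line))) {
      close_list(); out <- c(out, paste0("<p>", esc(line), "</p>"))
    } else {
      close_list()
    }
    i <- i + 1
  }
  close_list()
  paste(c(out, "</body></html>"), collapse = "\n")
}
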