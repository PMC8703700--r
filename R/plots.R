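#' Plot a geometry error series
#'
#' One panel per check: the per-frame error (reconstructed minus nominal)
#' over time, in mm for distance checks and degrees for angle checks.
#'
#' @param object A `qc_series` from [measure_geometry()] and friends.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_series
#' @export
autoplot.qc_series <- function(object, ...) {
  df <- dplyr::filter(object, .data$valid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$error)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~check_id, scales = "free_y") +
    ggplot2::labs(x = "time (s)",
                  y = "error (mm for distances, deg for angles)") +
    ggplot2::theme_minimal()
}

#' Plot the per-check summaries of a QC report
#'
#' Bar chart of the expanded uncertainties (static) and RMSEs (dynamic) per
#' check, faceted by phase and check type.
#'
#' @param object A `qc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$check_id, y = .data$value,
                                   fill = .data$check_type)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(check_type ~ phase, scales = "free") +
    ggplot2::labs(x = NULL, y = "expanded uncertainty / RMSE (mm, deg)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
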