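#' Plot normalized viability traces of a plate
#'
#' One line per well, coloured by role, control-normalized viability
#' against time.
#'
#' @param traces Output of [normalize_traces()] (or the `traces` element
#'   of a `plate_analysis`).
#' @param y Column to plot: `"pct_control"` (default), `"pct_baseline"` or
#'   `"raw_area_px"`.
#' @return A ggplot object.
#' @export
plot_viability_traces <- function(traces, y = "pct_control") {
  ggplot2::ggplot(traces,
                  ggplot2::aes(x = .data$time_min / 60, y = .data[[y]],
                               group = .data$well, colour = .data$role)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (h)", y = y) +
    ggplot2::theme_minimal()
}

#' Dose-response curves over time
#'
#' The standard drug-profiling layout: one viability-versus-time curve per
#' concentration, faceted by drug.
#'
#' @param surface A `dose_surface`.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(surface) {
  ggplot2::ggplot(surface,
                  ggplot2::aes(x = .data$time_min / 60, y = .data$viability,
                               colour = factor(.data$dose_nM),
                               group = .data$dose_nM)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$drug)) +
    ggplot2::labs(x = "time (h)", y = "viability (% of control)",
                  colour = "dose (nM)") +
    ggplot2::theme_minimal()
}

#' @method autoplot dose_surface
#' @export
autoplot.dose_surface <- function(object, ...) plot_dose_response(object)

#' @method autoplot viability_trace
#' @export
autoplot.viability_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min / 60,
                                       y = .data$raw_area_px)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "live area (px)") +
    ggplot2::theme_minimal()
}
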