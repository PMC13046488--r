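#' Tidy a dose-response surface
#'
#' @param x A `dose_surface`.
#' @param ... Unused.
#' @return The surface as a plain tibble.
#' @method tidy dose_surface
#' @export
tidy.dose_surface <- function(x, ...) as_tibble(x)

#' @rdname tidy.dose_surface
#' @method glance dose_surface
#' @export
glance.dose_surface <- function(x, ...) {
  tibble(n_samples = dplyr::n_distinct(x$sample),
         n_drugs = dplyr::n_distinct(x$drug),
         n_doses = dplyr::n_distinct(x$dose_nM),
         n_times = dplyr::n_distinct(x$time_min),
         t_min_h = min(x$time_min) / 60, t_max_h = max(x$time_min) / 60,
         n_incomplete = length(attr(x, "incomplete")))
}

#' Tidy a QC report
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return Per-sample verdict tibble.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) x$samples

#' @rdname tidy.qc_report
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble(qc_time_h = x$qc_time_h,
         n_samples = nrow(x$samples),
         n_valid = sum(x$samples$verdict == "valid"),
         n_conditional = sum(x$samples$verdict == "conditional_valid"),
         n_invalid = sum(x$samples$verdict == "invalid"))
}

#' Tidy a plate analysis
#'
#' @param x A `plate_analysis`.
#' @param ... Unused.
#' @return The per-drug summary tibble.
#' @method tidy plate_analysis
#' @export
tidy.plate_analysis <- function(x, ...) x$summary

#' @rdname tidy.plate_analysis
#' @method glance plate_analysis
#' @export
glance.plate_analysis <- function(x, ...) {
  dplyr::bind_cols(glance(x$qc),
                   tibble(n_wells = dplyr::n_distinct(x$traces$well),
                          n_missing = length(x$missing_wells)))
}
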