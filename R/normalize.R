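#' Normalize a viability trace to its own baseline
#'
#' First normalization step: every raw area value of a well is divided by
#' the same well's value at frame index `W` (the first frame with a
#' complete motion window, 3 h in with the defaults), which is defined as
#' 100\% viability. This absorbs the well-to-well variation in how many
#' cells were actually photographed.
#'
#' @param trace A `viability_trace` (or tibble with `frame`,
#'   `raw_area_px`).
#' @param config [acq_config()]; `motion_window` names the baseline frame.
#' @return The trace with a `pct_baseline` column. A zero baseline flags
#'   the well `static_start` (attribute) and yields `NA` percentages.
#' @export
normalize_within_well <- function(trace, config = acq_config()) {
  W <- config$motion_window
  i <- which(trace$frame == W)
  if (!length(i)) stop("trace has no value at baseline frame index ", W)
  baseline <- trace$raw_area_px[i[1]]
  if (baseline <= 0) {
    trace$pct_baseline <- NA_real_
    attr(trace, "static_start") <- TRUE
    return(trace)
  }
  trace$pct_baseline <- 100 * trace$raw_area_px / baseline
  attr(trace, "static_start") <- FALSE
  trace
}

#' Normalize a well trace to the vehicle-control mean
#'
#' Second normalization step: the baseline-normalized viability of a well
#' at each time point is divided by the mean baseline-normalized viability
#' of the vehicle-control replicates at the same time point, removing
#' drug-independent death or proliferation. The reference layout carries
#' 10 vehicle wells; at least 2 usable ones are required.
#'
#' @param trace Tibble with `frame` and `pct_baseline`.
#' @param controls List of control tibbles with `frame` and `pct_baseline`.
#' @param eps Control means at or below this are treated as undefined.
#' @return `trace` with a `pct_control` column (`NA` where fewer than two
#'   controls have values or the control mean vanishes).
#' @export
normalize_to_control <- function(trace, controls, eps = 1e-9) {
  if (length(controls) < 2) stop("need at least 2 usable control series")
  ctrl <- dplyr::bind_rows(controls) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(ctrl_mean = mean(.data$pct_baseline),
                     n_ctrl = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(trace, ctrl, by = "frame") |>
    dplyr::mutate(pct_control = dplyr::if_else(
      .data$n_ctrl >= 2 & .data$ctrl_mean > eps,
      100 * .data$pct_baseline / .data$ctrl_mean, NA_real_)) |>
    dplyr::select(-"ctrl_mean", -"n_ctrl")
  out
}

#' Apply both normalization steps across a plate
#'
#' Takes the long per-well raw traces, normalizes each well to its own
#' baseline, flags static-start wells (zero baseline, baseline under the
#' noise floor, or under 5\% of the median vehicle-control baseline of the
#' same sample - the quantitative proxy for the visual inspection of wells
#' that start out largely non-viable), and divides by the per-sample
#' vehicle-control mean at each time point. Flagged control wells are
#' excluded from the control mean.
#'
#' @param traces Tibble `(well, frame, time_min, raw_area_px)`.
#' @param layout A `plate_layout`.
#' @param config [acq_config()].
#' @return Tibble adding `role`, `drug`, `concentration_nM`, `replicate`,
#'   `sample`, `pct_baseline`, `pct_control`, `static_start`.
#' @export
normalize_traces <- function(traces, layout, config = acq_config()) {
  W <- config$motion_window
  df <- dplyr::inner_join(traces,
                          as_tibble(layout)[, c("well", "role", "drug",
                                                "concentration_nM",
                                                "replicate", "sample")],
                          by = "well")
  base <- df |>
    dplyr::filter(.data$frame == W) |>
    dplyr::select("well", baseline_px = "raw_area_px")
  df <- dplyr::left_join(df, base, by = "well")

  ctrl_base <- df |>
    dplyr::filter(.data$role == "vehicle_control", .data$frame == W) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(median_ctrl_baseline = median(.data$raw_area_px),
                     .groups = "drop")
  df <- dplyr::left_join(df, ctrl_base, by = "sample") |>
    dplyr::mutate(
      static_start = .data$baseline_px <= 0 |
        (!is.na(.data$median_ctrl_baseline) &
           .data$baseline_px < 0.05 * .data$median_ctrl_baseline),
      pct_baseline = dplyr::if_else(.data$static_start, NA_real_,
                                    100 * .data$raw_area_px / .data$baseline_px)
    )

  usable_ctrl <- df |>
    dplyr::filter(.data$role == "vehicle_control", !.data$static_start)
  ctrl <- usable_ctrl |>
    dplyr::group_by(.data$sample, .data$frame) |>
    dplyr::summarise(ctrl_mean = mean(.data$pct_baseline),
                     n_ctrl = dplyr::n(), .groups = "drop")
  # positive-control wells (a sensitive cell line) have no vehicle wells of
  # their own sample; they normalize against the plate-wide control mean
  plate_ctrl <- usable_ctrl |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(plate_mean = mean(.data$pct_baseline),
                     plate_n = dplyr::n(), .groups = "drop")
  df <- dplyr::left_join(df, ctrl, by = c("sample", "frame")) |>
    dplyr::left_join(plate_ctrl, by = "frame") |>
    dplyr::mutate(
      ctrl_mean = dplyr::if_else(.data$role == "positive_control" &
                                   is.na(.data$ctrl_mean),
                                 .data$plate_mean, .data$ctrl_mean),
      n_ctrl = dplyr::if_else(.data$role == "positive_control" &
                                is.na(.data$n_ctrl),
                              .data$plate_n, .data$n_ctrl),
      pct_control = dplyr::if_else(
        !is.na(.data$ctrl_mean) & .data$n_ctrl >= 2 & .data$ctrl_mean > 1e-9,
        100 * .data$pct_baseline / .data$ctrl_mean, NA_real_)) |>
    dplyr::select(-"baseline_px", -"median_ctrl_baseline", -"ctrl_mean",
                  -"n_ctrl", -"plate_mean", -"plate_n")
  df
}

#' Assay validity from control viability
#'
#' Per sample, the mean vehicle-control baseline viability at the QC time
#' (nearest acquired frame at or before 60 h by default) decides the
#' verdict: at or above 60\% the assay is valid; at or below 50\% it is
#' discarded as poorly representative of the seeded population; in the
#' open interval (50, 60) it is conditionally valid provided an
#' appropriate dose-response pattern is seen. That pattern check is
#' operationalized as: among drugs showing any effect (endpoint viability
#' at the top dose below 75\%), at least half have endpoint viability
#' non-increasing in dose with Spearman rank correlation <= -0.8. Samples
#' whose control wells all start static are invalid outright.
#'
#' @param norm_traces Output of [normalize_traces()].
#' @param layout A `plate_layout`.
#' @param config [acq_config()].
#' @param surfaces Optional [build_surface()] output used for the
#'   conditional band; without it a conditional sample cannot be confirmed
#'   and is reported invalid.
#' @param spearman_cut Rank-correlation threshold for the pattern check.
#' @param effect_cut Endpoint top-dose viability (\%) below which a drug
#'   counts as showing an effect.
#' @return A `qc_report`: list with per-sample tibble `samples`
#'   `(sample, control_viability_at_qc, n_controls, n_static_start,
#'   verdict, reason)` plus `qc_time_h` and per-well registration flags.
#' @export
evaluate_qc <- function(norm_traces, layout, config = acq_config(),
                        surfaces = NULL, spearman_cut = -0.8,
                        effect_cut = 75) {
  ctrl <- norm_traces |> dplyr::filter(.data$role == "vehicle_control")
  samples <- unique(as_tibble(layout)$sample[layout$role == "treatment"])
  if (!length(samples)) samples <- unique(ctrl$sample)
  rows <- lapply(samples, function(s) {
    cs <- ctrl |> dplyr::filter(.data$sample == s)
    n_static <- cs |> dplyr::distinct(.data$well, .data$static_start) |>
      dplyr::pull("static_start") |> sum()
    n_ctrl <- dplyr::n_distinct(cs$well)
    usable <- cs |> dplyr::filter(!.data$static_start)
    if (!nrow(usable)) {
      return(tibble(sample = s, control_viability_at_qc = NA_real_,
                    n_controls = n_ctrl, n_static_start = n_static,
                    verdict = "invalid",
                    reason = "controls largely non-viable at start"))
    }
    qc_time_min <- max(usable$time_min[usable$time_min <= config$qc_time * 60])
    v <- usable |> dplyr::filter(.data$time_min == qc_time_min) |>
      dplyr::pull("pct_baseline") |> mean()
    if (v >= 60) {
      verdict <- "valid"; reason <- "control viability >= 60% at QC time"
    } else if (v <= 50) {
      verdict <- "invalid"; reason <- "control viability <= 50% at QC time"
    } else if (dose_response_pattern_ok(surfaces, s, spearman_cut, effect_cut)) {
      verdict <- "conditional_valid"
      reason <- "control viability in (50, 60]; dose-response pattern confirmed"
    } else {
      verdict <- "invalid"
      reason <- "control viability in (50, 60]; dose-response pattern not confirmed"
    }
    tibble(sample = s, control_viability_at_qc = v, n_controls = n_ctrl,
           n_static_start = n_static, verdict = verdict, reason = reason)
  })
  structure(list(samples = dplyr::bind_rows(rows),
                 qc_time_h = config$qc_time),
            class = "qc_report")
}

dose_response_pattern_ok <- function(surfaces, sample, spearman_cut,
                                     effect_cut) {
  if (is.null(surfaces) || !nrow(surfaces)) return(FALSE)
  endpoint <- surfaces |>
    dplyr::filter(.data$sample == .env$sample) |>
    dplyr::group_by(.data$drug) |>
    dplyr::filter(.data$time_min == max(.data$time_min)) |>
    dplyr::ungroup()
  if (!nrow(endpoint)) return(FALSE)
  per_drug <- endpoint |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      has_effect = .data$viability[which.max(.data$dose_nM)] < effect_cut,
      rho = if (dplyr::n() >= 3) {
        suppressWarnings(stats::cor(.data$dose_nM, .data$viability,
                                    method = "spearman"))
      } else NA_real_,
      .groups = "drop") |>
    dplyr::filter(.data$has_effect)
  if (!nrow(per_drug)) return(FALSE)
  mean(per_drug$rho <= spearman_cut, na.rm = TRUE) >= 0.5
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> control viability judged at %g h\n", x$qc_time_h))
  print(x$samples)
  invisible(x)
}

#' Sample exclusion rate of a screen
#'
#' Percentage of screened samples failing the viability quality criteria;
#' summaries report it to the nearest integer percent (6 failures among 31
#' samples: 19\%).
#'
#' @param n_screened,n_failed Counts, `0 <= n_failed <= n_screened`.
#' @return Exact percentage (numeric); round for reporting.
#' @export
triage_exclusion_rate <- function(n_screened, n_failed) {
  stopifnot(n_screened > 0, n_failed >= 0, n_failed <= n_screened)
  100 * n_failed / n_screened
}
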