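#' Build a dose-time-response surface per drug
#'
#' Aggregates control-normalized treatment-well traces into a
#' replicate-averaged viability surface over (dose x time) for every
#' (sample, drug). Replicate spread (range) is recorded; cells backed by a
#' single replicate are flagged.
#'
#' @param norm_traces Output of [normalize_traces()] (must contain
#'   `pct_control`). Only `role == "treatment"` rows are used; passing
#'   exclusively non-treatment rows is an error.
#' @param layout A `plate_layout` (used to detect drugs with missing
#'   doses, which are flagged incomplete).
#' @return A `dose_surface` tibble `(sample, drug, dose_nM, frame,
#'   time_min, viability, spread, n_rep, single_replicate)` with attribute
#'   `incomplete` listing flagged drugs.
#' @export
build_surface <- function(norm_traces, layout = NULL) {
  tr <- norm_traces |> dplyr::filter(.data$role == "treatment")
  if (!nrow(tr)) stop("no treatment wells in input (role must be treatment)")
  surf <- tr |>
    dplyr::filter(!is.na(.data$pct_control)) |>
    dplyr::group_by(.data$sample, .data$drug, dose_nM = .data$concentration_nM,
                    .data$frame, .data$time_min) |>
    dplyr::summarise(viability = mean(.data$pct_control),
                     spread = diff(range(.data$pct_control)),
                     n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(single_replicate = .data$n_rep < 2) |>
    dplyr::arrange(.data$sample, .data$drug, .data$dose_nM, .data$frame)

  incomplete <- character()
  if (!is.null(layout)) {
    planned <- as_tibble(layout) |>
      dplyr::filter(.data$role == "treatment") |>
      dplyr::distinct(.data$sample, .data$drug, dose_nM = .data$concentration_nM)
    have <- surf |> dplyr::distinct(.data$sample, .data$drug, .data$dose_nM)
    missing <- dplyr::anti_join(planned, have,
                                by = c("sample", "drug", "dose_nM"))
    incomplete <- unique(missing$drug)
  }
  structure(surf, class = c("dose_surface", class(tibble())),
            incomplete = incomplete)
}

#' LD50 with censoring at the dose range
#'
#' The concentration at which control-normalized viability crosses 50\% at
#' the evaluation time, interpolated linearly in log10 dose between the
#' bracketing tested doses. Censoring follows the screen convention: if
#' viability at the highest tested dose still exceeds 50\%, the LD50 is
#' set to twice the highest tested concentration and flagged censored. If
#' viability is already below 50\% at the lowest dose, the lowest dose is
#' reported with a `below_range` flag (no extrapolation). A non-monotone
#' curve with several crossings uses the lowest-dose crossing and is
#' flagged.
#'
#' @param surface A `dose_surface`.
#' @param time_h Evaluation time in hours; `NULL` takes the last acquired
#'   frame. The nearest acquired frame at or before the requested time is
#'   used.
#' @return Tibble `(sample, drug, time_h, ld50_nM, ld50_censored,
#'   below_range, nonmonotone)`.
#' @export
ld50 <- function(surface, time_h = NULL) {
  eval_rows <- surface_at_time(surface, time_h)
  eval_rows |>
    dplyr::group_by(.data$sample, .data$drug) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$dose_nM)
      res <- ld50_from_curve(g$dose_nM, g$viability)
      tibble(time_h = g$time_min[1] / 60, ld50_nM = res$ld50,
             ld50_censored = res$censored, below_range = res$below_range,
             nonmonotone = res$nonmonotone)
    }) |>
    dplyr::ungroup()
}

# 50% crossing on a (dose, viability) curve; doses ascending
ld50_from_curve <- function(doses, viability) {
  stopifnot(length(doses) == length(viability), !is.unsorted(doses))
  n <- length(doses)
  out <- list(ld50 = NA_real_, censored = FALSE, below_range = FALSE,
              nonmonotone = FALSE)
  if (viability[n] > 50) {
    out$ld50 <- 2 * doses[n]
    out$censored <- TRUE
    return(out)
  }
  exact <- which(viability == 50)
  if (length(exact)) {
    out$ld50 <- doses[exact[1]]
    return(out)
  }
  if (viability[1] < 50) {
    out$ld50 <- doses[1]
    out$below_range <- TRUE
    return(out)
  }
  cross <- which(viability[-n] >= 50 & viability[-1] < 50)
  out$nonmonotone <- length(cross) > 1
  i <- cross[1]
  f <- (viability[i] - 50) / (viability[i] - viability[i + 1])
  out$ld50 <- 10^(log10(doses[i]) + f * (log10(doses[i + 1]) - log10(doses[i])))
  out
}

surface_at_time <- function(surface, time_h = NULL) {
  times <- sort(unique(surface$time_min))
  target <- if (is.null(time_h)) max(times) else {
    ok <- times[times <= time_h * 60 + 1e-9]
    if (!length(ok)) stop("surface has no frame at or before ", time_h, " h")
    max(ok)
  }
  surface |> dplyr::filter(.data$time_min == target)
}

#' Area under the dose-time-response surface
#'
#' For each dose, the trapezoidal integral of viability/100 over time,
#' normalized by the integrated duration to `[0, 1]`; the per-dose values
#' are then averaged over the tested doses. 1 means no drug effect at any
#' dose or time, 0 instant total kill.
#'
#' @param surface A `dose_surface`.
#' @return Tibble `(sample, drug, auc)`.
#' @export
auc <- function(surface) {
  surface |>
    dplyr::group_by(.data$sample, .data$drug, .data$dose_nM) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$time_min)
      if (nrow(g) < 2) stop("AUC undefined for a single time point")
      span <- max(g$time_min) - min(g$time_min)
      tibble(auc_dose = pracma::trapz(g$time_min, g$viability / 100) / span)
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$sample, .data$drug) |>
    dplyr::summarise(auc = mean(.data$auc_dose), .groups = "drop")
}

#' Per-drug summary table (LD50 + AUC)
#'
#' @param surface A `dose_surface`.
#' @param time_h LD50 evaluation time (hours); `NULL` = endpoint.
#' @return Tibble `(sample, drug, time_h, ld50_nM, ld50_censored,
#'   below_range, nonmonotone, auc, incomplete)`.
#' @export
drug_summary <- function(surface, time_h = NULL) {
  out <- dplyr::left_join(ld50(surface, time_h), auc(surface),
                          by = c("sample", "drug"))
  out$incomplete <- out$drug %in% attr(surface, "incomplete")
  out
}

#' Triage a drug library by minimal active concentration
#'
#' Splits a library into three disjoint sets: drugs inactive in every
#' sample at the highest tested concentration (`discarded_inactive`),
#' drugs active only above the preselection threshold (`discarded_weak`),
#' and drugs active at or below the threshold in at least one sample
#' (`preselected`). With the reference threshold of 0.5 uM, a 166-drug
#' library with 57 drugs inactive everywhere and 49 active only above
#' threshold leaves 60 preselected.
#'
#' @param activity Tibble `(drug, sample, min_active_nM)`;
#'   `NA` or `Inf` marks a drug inactive in that sample.
#' @param threshold_nM Preselection threshold (default 500 nM = 0.5 uM).
#' @return Tibble `(drug, category)` with `category` one of the three set
#'   names; attribute `counts` holds the per-set sizes.
#' @export
triage_panel <- function(activity, threshold_nM = 500) {
  stopifnot(all(c("drug", "sample", "min_active_nM") %in% names(activity)))
  conc <- activity$min_active_nM
  if (any(conc[is.finite(conc)] < 0)) stop("negative concentrations")
  per_drug <- activity |>
    dplyr::mutate(min_active_nM = dplyr::if_else(is.na(.data$min_active_nM),
                                                 Inf, .data$min_active_nM)) |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(best = min(.data$min_active_nM), .groups = "drop") |>
    dplyr::mutate(category = dplyr::case_when(
      is.infinite(.data$best) ~ "discarded_inactive",
      .data$best <= threshold_nM ~ "preselected",
      TRUE ~ "discarded_weak"
    )) |>
    dplyr::select("drug", "category")
  counts <- table(factor(per_drug$category,
                         levels = c("discarded_inactive", "discarded_weak",
                                    "preselected")))
  structure(per_drug, counts = c(counts))
}
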