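#' Correlate two per-sample response profiles
#'
#' Pearson product-moment correlation (rank-based variant via
#' `method = "spearman"`) between paired per-sample responses, e.g. LD50
#' vectors of two drugs of the same class. Censored LD50 values are
#' expected to be encoded at their censoring value (twice the top dose)
#' upstream, or excluded by the caller.
#'
#' @param x,y Paired numeric vectors, `n >= 3` after NA removal.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble `(estimate, p_value, n, method, flag)`; zero variance in
#'   either vector yields `NA` with `flag = "zero_variance"`.
#' @export
profile_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble(estimate = NA_real_, p_value = NA_real_, n = length(x),
                  method = method, flag = "zero_variance"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x),
         method = method, flag = NA_character_)
}

#' Event time from a leukemia-burden series
#'
#' Event-free survival for a xenografted mouse: the first day the hCD45
#' percentage in peripheral blood reaches the threshold (default 25\%),
#' with values between measurements interpolated linearly, or the day of
#' leukemia-related morbidity, whichever comes first. A series that never
#' crosses and has no morbidity is censored at the last observation.
#'
#' @param day Measurement days, strictly increasing.
#' @param hcd45 hCD45 percentages in `[0, 100]`, same length.
#' @param threshold Event threshold in percent, inside (0, 100).
#' @param morbidity_day Optional day of morbidity.
#' @return List `(time, event)`; `event = FALSE` means censored.
#' @export
event_time <- function(day, hcd45, threshold = 25, morbidity_day = NULL) {
  if (threshold <= 0 || threshold >= 100) stop("threshold must be inside (0, 100)")
  stopifnot(length(day) == length(hcd45), length(day) >= 1)
  if (any(diff(day) <= 0)) stop("measurement days must be strictly increasing")
  if (any(hcd45 < 0 | hcd45 > 100)) stop("hCD45 must be within [0, 100]")

  cross_day <- NA_real_
  if (hcd45[1] >= threshold) {
    cross_day <- day[1]
  } else {
    i <- which(hcd45[-1] >= threshold & hcd45[-length(hcd45)] < threshold)
    if (length(i)) {
      i <- i[1]
      f <- (threshold - hcd45[i]) / (hcd45[i + 1] - hcd45[i])
      cross_day <- day[i] + f * (day[i + 1] - day[i])
    }
  }
  candidates <- c(cross_day, morbidity_day %||% NA_real_)
  if (all(is.na(candidates))) {
    return(list(time = day[length(day)], event = FALSE))
  }
  list(time = min(candidates, na.rm = TRUE), event = TRUE)
}

#' Event times for a cohort table
#'
#' Tidy wrapper over [event_time()]: one row per mouse.
#'
#' @param cohort Tibble with columns `mouse`, `day`, `hcd45`, optionally
#'   `group` and a per-mouse `morbidity_day`.
#' @inheritParams event_time
#' @return Tibble `(mouse, group, time, event)`.
#' @export
event_times <- function(cohort, threshold = 25) {
  cohort |>
    dplyr::group_by(.data$mouse) |>
    dplyr::group_modify(function(g, key) {
      md <- if ("morbidity_day" %in% names(g)) {
        v <- unique(g$morbidity_day[!is.na(g$morbidity_day)])
        if (length(v)) v[1] else NULL
      } else NULL
      et <- event_time(g$day, g$hcd45, threshold, md)
      tibble(group = if ("group" %in% names(g)) g$group[1] else NA_character_,
             time = et$time, event = et$event)
    }) |>
    dplyr::ungroup()
}

#' Leukemia growth-delay ratio
#'
#' Median event-free survival of drug-treated mice divided by that of
#' control mice. Censored animals enter at their censoring day; when a
#' censored time is at or above the group median the ratio is flagged as
#' censoring-dominated.
#'
#' @param treated,control Numeric event/censoring times (days).
#' @param treated_event,control_event Optional logical event indicators
#'   (`FALSE` = censored); default all events.
#' @return List `(ratio, censored_dominates)`.
#' @export
growth_delay_ratio <- function(treated, control,
                               treated_event = NULL, control_event = NULL) {
  stopifnot(length(treated) >= 1, length(control) >= 1)
  treated_event <- treated_event %||% rep(TRUE, length(treated))
  control_event <- control_event %||% rep(TRUE, length(control))
  mc <- median(control)
  if (mc == 0) stop("control median EFS is zero; ratio undefined")
  mt <- median(treated)
  dominated <- any(!treated_event & treated >= mt) ||
    any(!control_event & control >= mc)
  list(ratio = mt / mc, censored_dominates = dominated)
}

#' Rank correlation between ex vivo sensitivity and in vivo outcome
#'
#' Spearman correlation between per-sample LD50 values and per-sample
#' leukemia growth-delay ratios. Censored LD50s are expected encoded at
#' twice the highest tested concentration (the screen convention).
#'
#' @param ld50s,ratios Paired numeric vectors, `n >= 3`.
#' @return Tibble `(estimate, p_value, n, method, flag)`; exhausted ranks
#'   (all-tied input) are flagged.
#' @export
sensitivity_vs_outcome <- function(ld50s, ratios) {
  res <- profile_correlation(ld50s, ratios, method = "spearman")
  if (!is.na(res$flag[1]) || length(unique(rank(ld50s))) == 1 ||
      length(unique(rank(ratios))) == 1) {
    res$flag <- "zero_variance"
  }
  res
}

#' Long-format screen matrix
#'
#' Binds per-plate drug summaries into the screen-level
#' samples x drugs matrix in long form, carrying censoring flags through.
#'
#' @param summaries List of [drug_summary()] tibbles (or one tibble).
#' @return Tibble `(sample, drug, ld50_nM, ld50_censored, auc)`.
#' @export
screen_matrix <- function(summaries) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  dplyr::bind_rows(summaries) |>
    dplyr::select("sample", "drug", "ld50_nM", "ld50_censored", "auc")
}
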