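#' Run the full per-plate analysis
#'
#' Orchestrates the whole pipeline for one plate: per-well drift
#' registration, motion-based viability tracing, the two normalization
#' steps, assay QC, dose-response surfaces and the per-drug LD50/AUC
#' summary. Positive-control wells are traced and normalized like
#' treatment wells but excluded from dose-response fitting; they only feed
#' a per-drug activity annotation in the QC report (endpoint viability
#' below 50\% at the top dose marks the drug active/stable). The run is
#' deterministic: identical inputs give identical outputs.
#'
#' @param stacks Named list of `frame_stack`s keyed by well address; every
#'   non-empty layout well should have one. A missing treatment stack
#'   flags that drug incomplete and the run continues.
#' @param layout A `plate_layout`.
#' @param config [acq_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `traces.csv`, `qc.json`, `drug_summary.csv`, `shifts.csv` and one
#'   endpoint overlay PNG per well.
#' @return A `plate_analysis` list: `traces` (long tibble with raw and
#'   normalized series), `qc` (a `qc_report`), `surface` (a
#'   `dose_surface`), `summary` (the [drug_summary()] tibble),
#'   `positive_controls`, and `missing_wells`.
#' @export
run_plate_analysis <- function(stacks, layout, config = acq_config(),
                               out_dir = NULL) {
  wells <- as_tibble(layout) |> dplyr::filter(.data$role != "empty")
  missing <- setdiff(wells$well, names(stacks))
  if (length(missing)) {
    warning("no stack for well(s): ", paste(missing, collapse = ", "),
            "; affected drugs flagged incomplete")
  }
  traces <- list(); shifts <- list(); masks <- list()
  for (wname in intersect(wells$well, names(stacks))) {
    st <- stacks[[wname]]
    if (config$registration) {
      st <- register_stack(st, config)
      shifts[[wname]] <- shift_table(st) |> dplyr::mutate(well = wname)
    }
    vt <- viability_trace(st, config, keep_layers = !is.null(out_dir))
    if (!is.null(out_dir)) {
      layers <- attr(vt, "layers")
      last <- layers[[length(layers)]]
      masks[[wname]] <- list(frame = st$frames[, , dim(st$frames)[3]],
                             mask = last$mask)
    }
    traces[[wname]] <- as_tibble(vt) |> dplyr::mutate(well = wname)
  }
  raw <- dplyr::bind_rows(traces) |>
    dplyr::select("well", "frame", "time_min", "raw_area_px")
  norm <- normalize_traces(raw, layout, config)

  surface <- tryCatch(build_surface(norm, layout), error = function(e) NULL)
  if (!is.null(surface) && length(missing)) {
    miss_drugs <- unique(wells$drug[wells$well %in% missing &
                                      wells$role == "treatment"])
    attr(surface, "incomplete") <-
      unique(c(attr(surface, "incomplete"), miss_drugs[!is.na(miss_drugs)]))
  }
  qc <- evaluate_qc(norm, layout, config, surfaces = surface)
  summary <- if (!is.null(surface)) drug_summary(surface, config$eval_time)
             else tibble(sample = character(), drug = character(),
                         time_h = numeric(), ld50_nM = numeric(),
                         ld50_censored = logical(), below_range = logical(),
                         nonmonotone = logical(), auc = numeric(),
                         incomplete = logical())
  pos <- positive_control_flags(norm)

  res <- structure(list(traces = norm, qc = qc, surface = surface,
                        summary = summary, positive_controls = pos,
                        missing_wells = missing, config = config),
                   class = "plate_analysis")
  if (!is.null(out_dir)) write_plate_outputs(res, masks,
                                             dplyr::bind_rows(shifts), out_dir)
  res
}

positive_control_flags <- function(norm) {
  pc <- norm |> dplyr::filter(.data$role == "positive_control",
                              !is.na(.data$pct_control))
  if (!nrow(pc)) {
    return(tibble(drug = character(), endpoint_viability = numeric(),
                  active = logical()))
  }
  pc |>
    dplyr::group_by(.data$drug) |>
    dplyr::filter(.data$frame == max(.data$frame)) |>
    dplyr::summarise(endpoint_viability = mean(.data$pct_control),
                     .groups = "drop") |>
    dplyr::mutate(active = .data$endpoint_viability < 50)
}

write_plate_outputs <- function(res, masks, shifts, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$traces, file.path(out_dir, "traces.csv"), na = "")
  readr::write_csv(res$summary, file.path(out_dir, "drug_summary.csv"), na = "")
  if (nrow(shifts)) readr::write_csv(shifts, file.path(out_dir, "shifts.csv"))
  qc <- list(qc_time_h = res$qc$qc_time_h, samples = res$qc$samples,
             positive_controls = res$positive_controls,
             missing_wells = res$missing_wells)
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  for (wname in names(masks)) {
    render_overlay(masks[[wname]]$frame, masks[[wname]]$mask,
                   path = file.path(out_dir, paste0("overlay_", wname, ".png")))
  }
  invisible(out_dir)
}

#' @export
print.plate_analysis <- function(x, ...) {
  cat(sprintf("<plate_analysis> %d wells traced, %d drugs summarised\n",
              dplyr::n_distinct(x$traces$well), nrow(x$summary)))
  print(x$qc)
  invisible(x)
}
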