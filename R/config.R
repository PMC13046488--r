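#' Acquisition and analysis configuration
#'
#' Bundles the acquisition geometry and every tunable analysis parameter of
#' the motion-viability pipeline. Defaults correspond to the reference assay:
#' one bright-field image per well every 30 minutes for 96 hours at
#' 2,048 x 1,536 px (5x objective), with membrane motion integrated over a
#' trailing six-frame (3 h) window.
#'
#' @param frame_interval Minutes between consecutive frames. Default 30.
#' @param total_duration Imaging span in hours. Default 96; runs of 80-96 h
#'   are typical and all time lookups pick the nearest acquired frame at or
#'   before the requested time.
#' @param frame_height,frame_width Frame geometry in pixels.
#' @param motion_window Number of trailing frames `W` pooled by the running
#'   maximum projection. The first viability value is defined at frame index
#'   `W` (0-based), i.e. 3 h after imaging starts with the defaults.
#' @param qc_time Hour at which vehicle-control viability is judged for
#'   assay validity. Default 60.
#' @param cell_radius Nominal blast radius in pixels at the working
#'   magnification. Drives the blur width and background radius defaults.
#' @param background_radius Structuring-element radius (px) of the grayscale
#'   opening used as rolling-ball-style background estimate. Must exceed a
#'   cell diameter so cells are flattened out of the background.
#' @param blur_sigma Gaussian sigma (px) used to merge motion rings into
#'   solid spots. Default `cell_radius / 2`.
#' @param k_rel Relative threshold: fraction of the 99.9th percentile of the
#'   blurred difference image. Gives intensity-scale invariance.
#' @param k_abs Absolute threshold floor. `NULL` (default) estimates it from
#'   a cell-free border region of the stack, suppressing noise in empty wells.
#' @param border_px Width of the border strip used for the noise-floor
#'   estimate.
#' @param max_shift Registration shifts (px) beyond this are flagged.
#'   Default 10\% of the smaller frame dimension.
#' @param reg_mode `"chain"` (each frame against its predecessor, shifts
#'   accumulated; robust to slow content change) or `"reference"` (each frame
#'   against the reference frame).
#' @param reg_deadband Shift estimates smaller than this (px) are zeroed
#'   (per step in chain mode, per frame in reference mode): live-cell
#'   membrane wobble leaks a small random component into each pairwise
#'   estimate, and integrating it would slowly blur a drift-free stack.
#'   Stage drift and vibration worth correcting exceed this scale.
#' @param subpixel Apply subpixel shifts by bilinear interpolation. `FALSE`
#'   rounds shifts to integers (bit-stable, useful in tests).
#' @param fill_holes Fill holes in thresholded components so each moving
#'   cell becomes one solid spot.
#' @param max_object_area Optional connected-component area cut (px); objects
#'   larger than this are dropped from the live mask. `Inf` (default)
#'   disables it; stromal cells are normally controlled by seeding few of
#'   them rather than by size gating.
#' @param eval_time Dose-response evaluation time in hours; `NULL` uses the
#'   last acquired frame.
#' @param registration Run drift registration before motion analysis.
#' @param background_mode `"stack"` (default) estimates one opening-based
#'   background envelope from the temporal median of the registered stack
#'   and subtracts it from every frame; `"frame"` re-estimates it per
#'   frame. The stack-level envelope cannot inject temporal variation of
#'   its own (a per-frame envelope follows the dark membrane rings as they
#'   move, leaking background fluctuation into the motion signal); the
#'   per-frame mode tracks slow illumination drift instead.
#'
#' @return An object of class `wm_config` (a validated list).
#' @examples
#' cfg <- acq_config()
#' expected_frames(cfg)
#' @export
acq_config <- function(frame_interval = 30,
                       total_duration = 96,
                       frame_height = 1536,
                       frame_width = 2048,
                       motion_window = 6L,
                       qc_time = 60,
                       cell_radius = 8,
                       background_radius = 50,
                       blur_sigma = NULL,
                       k_rel = 0.25,
                       k_abs = NULL,
                       border_px = 8,
                       max_shift = NULL,
                       reg_mode = c("chain", "reference"),
                       reg_deadband = 0.3,
                       subpixel = TRUE,
                       fill_holes = TRUE,
                       max_object_area = Inf,
                       eval_time = NULL,
                       registration = TRUE,
                       background_mode = c("stack", "frame")) {
  reg_mode <- match.arg(reg_mode)
  background_mode <- match.arg(background_mode)
  stopifnot(
    "frame_interval must be > 0" = frame_interval > 0,
    "total_duration must be > 0" = total_duration > 0,
    "motion_window must be >= 2" = motion_window >= 2,
    "frame dimensions must be positive" = frame_height > 0 && frame_width > 0,
    "k_rel must be in [0, 1]" = k_rel >= 0 && k_rel <= 1,
    "background_radius must be > 0" = background_radius > 0
  )
  cfg <- list(
    frame_interval = frame_interval,
    total_duration = total_duration,
    frame_height = frame_height,
    frame_width = frame_width,
    motion_window = as.integer(motion_window),
    qc_time = qc_time,
    cell_radius = cell_radius,
    background_radius = background_radius,
    blur_sigma = blur_sigma %||% (cell_radius / 2),
    k_rel = k_rel,
    k_abs = k_abs,
    border_px = border_px,
    max_shift = max_shift %||% (0.1 * min(frame_height, frame_width)),
    reg_mode = reg_mode,
    reg_deadband = reg_deadband,
    subpixel = subpixel,
    fill_holes = fill_holes,
    max_object_area = max_object_area,
    eval_time = eval_time,
    registration = registration,
    background_mode = background_mode
  )
  structure(cfg, class = "wm_config")
}

#' @export
print.wm_config <- function(x, ...) {
  cat("<wm_config>\n")
  cat(sprintf("  acquisition: every %g min for %g h (%d x %d px)\n",
              x$frame_interval, x$total_duration, x$frame_height, x$frame_width))
  cat(sprintf("  motion window: %d frames (%g h)\n",
              x$motion_window, x$motion_window * x$frame_interval / 60))
  cat(sprintf("  background radius %g px, blur sigma %g px, k_rel %g\n",
              x$background_radius, x$blur_sigma, x$k_rel))
  cat(sprintf("  registration: %s (%s)\n",
              if (x$registration) "on" else "off", x$reg_mode))
  invisible(x)
}

#' Number of frames acquired after time zero
#'
#' `total_duration / frame_interval`, the frame count a full run appends
#' after the time-zero image: 96 h at 30-min intervals gives 192 frames per
#' well (73,728 images across a 384-well plate).
#'
#' @param config A [acq_config()] object.
#' @return Integer frame count. Non-divisible durations round down with a
#'   warning.
#' @export
expected_frames <- function(config) {
  stopifnot(inherits(config, "wm_config"))
  n <- config$total_duration * 60 / config$frame_interval
  if (abs(n - round(n)) > 1e-9) {
    warning("total_duration is not a multiple of frame_interval; rounding down")
    n <- floor(n)
  }
  as.integer(round(n))
}

#' Read a run configuration from YAML or JSON
#'
#' The file may set any [acq_config()] field by name; unset fields keep
#' their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `wm_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(acq_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  }
  do.call(acq_config, vals)
}

# nearest acquired frame index (0-based) at or before `hours`
nearest_frame_at <- function(timestamps_min, hours) {
  ok <- which(timestamps_min <= hours * 60 + 1e-9)
  if (!length(ok)) stop("no acquired frame at or before ", hours, " h")
  max(ok) - 1L
}
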