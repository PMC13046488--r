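#' Construct a frame stack
#'
#' A `frame_stack` holds one well's grayscale time series as an
#' `H x W x T` array plus acquisition timestamps in minutes.
#'
#' @param frames Numeric array `H x W x T` (or a list of equal-size
#'   matrices), intensities finite and >= 0.
#' @param timestamps Minutes since imaging start, strictly increasing,
#'   length `T`. Defaults to `0, interval, 2*interval, ...`.
#' @param interval Frame interval in minutes, used when `timestamps` is NULL.
#' @param well Optional well annotation (a one-row slice of a
#'   `plate_layout`, or a well address string).
#' @return A `frame_stack`.
#' @export
frame_stack <- function(frames, timestamps = NULL, interval = 30, well = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("mixed page dimensions in stack")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  stopifnot("frames must be an H x W x T array" = length(dim(frames)) == 3)
  tn <- dim(frames)[3]
  timestamps <- timestamps %||% ((seq_len(tn) - 1) * interval)
  if (length(timestamps) != tn) stop("timestamps length must equal frame count")
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  if (any(!is.finite(frames)) || any(frames < 0)) {
    stop("intensities must be finite and >= 0")
  }
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 well = well),
            class = "frame_stack")
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %g-%g min%s\n",
              d[3], d[1], d[2], min(x$timestamps), max(x$timestamps),
              if (!is.null(x$well)) paste0(", well ", if (is.character(x$well)) x$well else x$well$well) else ""))
  invisible(x)
}

#' Read a multi-page TIFF time-lapse stack
#'
#' One grayscale page per time point, in acquisition order. Timestamps are
#' synthesized as `i * frame_interval` (TIFF metadata rarely stores them;
#' when a `timestamps` argument is supplied it wins).
#'
#' @param path TIFF file path.
#' @param config [acq_config()]; supplies `frame_interval` and the minimum
#'   page count (`motion_window`).
#' @param well,timestamps Optional annotations, see [frame_stack()].
#' @return A `frame_stack`.
#' @export
read_stack <- function(path, config = acq_config(), well = NULL,
                       timestamps = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # keep first channel
    p
  })
  if (length(pages) < config$motion_window) {
    stop("stack has ", length(pages), " pages; at least motion_window = ",
         config$motion_window, " are required")
  }
  frame_stack(pages, timestamps = timestamps,
              interval = config$frame_interval, well = well)
}

#' Write a frame stack as a multi-page grayscale TIFF
#'
#' Intensities are clipped to `[0, 1]` and stored as 16-bit pages.
#'
#' @param stack A `frame_stack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  fr <- stack$frames
  fr[fr > 1] <- 1
  pages <- lapply(seq_len(dim(fr)[3]), function(t) fr[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
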