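#' Remove smooth background illumination from a frame
#'
#' Grayscale morphological opening with a disc (a rolling-ball-style
#' envelope) estimates the smooth background, which is subtracted and the
#' result clipped at zero. Cells smaller than the disc survive as bright
#' objects on a dark background; illumination gradients and vignetting are
#' flattened out.
#'
#' @param frame Numeric matrix.
#' @param radius Disc radius in pixels; must exceed a cell diameter
#'   (default from [acq_config()]: 50 px at the 5x reference scale).
#' @return Background-subtracted matrix, `>= 0`.
#' @export
subtract_background <- function(frame, radius = 50) {
  if (radius <= 0) stop("background radius must be > 0")
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  bg <- EBImage::opening(frame, brush)
  out <- frame - bg
  out[out < 0] <- 0
  out
}

#' Trailing running-maximum projection
#'
#' For each frame index `t >= W - 1` (0-based), the per-pixel maximum over
#' the trailing window of `W` frames `t - W + 1 ... t`. Membrane positions
#' visited anywhere in the window stay bright in the projection; a later
#' subtraction of the current frame then isolates motion. With the default
#' `W = 6` at 30-min spacing the window spans 3 h.
#'
#' @param frames `H x W x T` array (or list of matrices), `T >= W`.
#' @param W Window length in frames, `>= 2`.
#' @return Array of the same shape; entries before the first complete
#'   window (`t < W - 1`, 0-based) are `NA`.
#' @export
running_max <- function(frames, W = 6) {
  if (W < 2) stop("motion window W must be >= 2")
  if (is.list(frames)) frames <- array(unlist(frames),
                                       dim = c(dim(frames[[1]]), length(frames)))
  tn <- dim(frames)[3]
  if (tn < W) stop("stack has ", tn, " frames; window needs at least ", W)
  out <- array(NA_real_, dim = dim(frames))
  for (t in W:tn) {
    acc <- frames[, , t - W + 1]
    for (k in (t - W + 2):t) acc <- pmax(acc, frames[, , k])
    out[, , t] <- acc
  }
  out
}

#' Motion difference image
#'
#' `maxproj - frame`, clipped at zero: bright exactly where intensity was
#' present somewhere in the trailing window but is absent from the current
#' frame. Actively moving membranes appear as bright rings; static (dead)
#' cells cancel exactly.
#'
#' @param maxproj,frame Equal-size matrices.
#' @return Non-negative difference matrix.
#' @export
motion_difference <- function(maxproj, frame) {
  stopifnot(all(dim(maxproj) == dim(frame)))
  out <- maxproj - frame
  out[out < 0] <- 0
  out
}

#' Convert motion rings into solid cell spots
#'
#' Gaussian blur merges each bright motion ring into a blob, which is then
#' binarized and hole-filled so every moving cell becomes one solid spot.
#' The threshold is `max(k_abs, k_rel * q999)` where `q999` is the 99.9th
#' percentile of the blurred image: the relative part makes the mask
#' invariant to global intensity scaling, the absolute floor keeps empty
#' wells empty.
#'
#' @param diff Non-negative difference image.
#' @param sigma Gaussian sigma in px (default: half the cell radius).
#' @param k_rel Relative threshold fraction.
#' @param k_abs Absolute threshold floor (same units as `diff`).
#' @param fill_holes Fill enclosed holes in each connected component.
#' @param max_object_area Drop connected components larger than this many
#'   pixels (`Inf` disables).
#' @return Logical mask matrix.
#' @export
rings_to_spots <- function(diff, sigma = 4, k_rel = 0.25, k_abs = 0,
                           fill_holes = TRUE, max_object_area = Inf) {
  if (sigma <= 0) stop("sigma must be > 0")
  blurred <- gblur_pad(diff, sigma)
  thr <- max(k_abs, k_rel * quantile(blurred, 0.999, names = FALSE))
  mask <- blurred > thr
  if (!any(mask)) return(mask)
  if (fill_holes) {
    mask <- EBImage::fillHull(EBImage::Image(mask)) > 0
  }
  if (is.finite(max_object_area)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes > max_object_area)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  mask
}

# gblur with replicated borders (EBImage gblur pads with zeros via
# "linear" boundary only in newer versions; pad manually to stay neutral
# at the frame edge)
gblur_pad <- function(x, sigma) {
  p <- ceiling(3 * sigma)
  h <- nrow(x); w <- ncol(x)
  xp <- x[c(rep(1, p), seq_len(h), rep(h, p)), c(rep(1, p), seq_len(w), rep(w, p))]
  g <- EBImage::gblur(xp, sigma = sigma)
  g[(p + 1):(p + h), (p + 1):(p + w)]
}

#' Per-frame live pixel area from membrane motion
#'
#' The core viability signal. Each registered frame is background
#' subtracted; a trailing running-maximum projection over `W` frames is
#' formed; the current frame is subtracted from the projection so moving
#' membranes leave bright rings; the rings are blurred and thresholded into
#' solid spots; and the live area is the total spot pixel count. Viability
#' is deliberately quantified as summed pixel area, not object count.
#'
#' The first defined value sits at frame index `W` (0-based) - 3 h after
#' imaging start with the defaults - matching the baseline convention of
#' [normalize_within_well()].
#'
#' The absolute threshold floor, when not set in `config`, is estimated
#' from the blurred difference values in a `border_px`-wide frame border
#' (largely cell-free): their pooled median + 5 MAD, which stays robust to
#' the occasional motile stromal cell crossing the strip. The relative
#' threshold term is evaluated once per well on the baseline window (first
#' three defined frames) and held fixed for the whole movie.
#'
#' @param stack A `registered_stack` (or plain `frame_stack`, e.g. when
#'   drift is known absent).
#' @param config [acq_config()].
#' @param keep_layers Retain intermediate images (background-subtracted,
#'   projection, difference, mask) for the defined frames.
#' @return A `viability_trace`: tibble `(frame, time_min, raw_area_px)`
#'   with `frame` 0-based starting at `W`; attributes `well`, `threshold`,
#'   `flags` and (optionally) `layers`.
#' @export
viability_trace <- function(stack, config = acq_config(), keep_layers = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  fr <- stack$frames
  tn <- dim(fr)[3]
  W <- config$motion_window
  if (tn < W + 1) stop("stack too short for motion window W = ", W)

  bsub <- array(0, dim = dim(fr))
  if (config$background_mode == "stack") {
    # one envelope for the whole (registered) stack: the opening of the
    # temporal median frame; a per-frame envelope would follow the moving
    # dark membrane rings and leak its own fluctuation into the signal
    med <- apply(fr, c(1, 2), median)
    brush <- EBImage::makeBrush(2L * as.integer(config$background_radius) + 1L,
                                shape = "disc")
    bg <- EBImage::opening(med, brush)
    for (t in seq_len(tn)) {
      d <- fr[, , t] - bg
      d[d < 0] <- 0
      bsub[, , t] <- d
    }
  } else {
    for (t in seq_len(tn)) {
      bsub[, , t] <- subtract_background(fr[, , t], config$background_radius)
    }
  }
  proj <- running_max(bsub, W)

  sigma <- config$blur_sigma
  idx <- (W + 1):tn  # 1-based; 0-based frame index W ... tn-1
  blurred <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    d <- motion_difference(proj[, , idx[i]], bsub[, , idx[i]])
    blurred[[i]] <- gblur_pad(d, sigma)
  }

  # noise floor from the border strip; median + 5 MAD stays robust to the
  # occasional motile stromal cell crossing the border
  k_abs <- config$k_abs
  if (is.null(k_abs)) {
    b <- config$border_px
    h <- dim(fr)[1]; w <- dim(fr)[2]
    border <- unlist(lapply(blurred, function(m) {
      c(m[c(seq_len(b), (h - b + 1):h), ], m[, c(seq_len(b), (w - b + 1):w)])
    }))
    k_abs <- median(border) + 5 * mad(border)
  }

  # the relative threshold is evaluated once, on the baseline window
  # (first three defined frames): one criterion for the whole movie.
  # Re-evaluating it per frame would relax the cut as cells die and
  # inflate late-frame live area in strongly responding wells.
  q999_base <- quantile(unlist(blurred[seq_len(min(3, length(blurred)))]),
                        0.999, names = FALSE)
  thr <- max(k_abs, config$k_rel * q999_base)

  areas <- integer(length(idx))
  layers <- if (keep_layers) vector("list", length(idx)) else NULL
  for (i in seq_along(idx)) {
    mask <- blurred[[i]] > thr
    if (any(mask) && config$fill_holes) {
      mask <- EBImage::fillHull(EBImage::Image(mask)) > 0
    }
    if (any(mask) && is.finite(config$max_object_area)) {
      lab <- EBImage::bwlabel(mask)
      sizes <- tabulate(lab[lab > 0])
      drop <- which(sizes > config$max_object_area)
      if (length(drop)) mask[lab %in% drop] <- FALSE
    }
    areas[i] <- sum(mask)
    if (keep_layers) {
      layers[[i]] <- list(background_subtracted = bsub[, , idx[i]],
                          projection = proj[, , idx[i]],
                          blurred_difference = blurred[[i]],
                          mask = mask)
    }
  }

  out <- tibble(frame = idx - 1L, time_min = stack$timestamps[idx],
                raw_area_px = areas)
  structure(out,
            class = c("viability_trace", class(tibble())),
            well = stack$well,
            threshold = c(k_abs = k_abs, k_rel = config$k_rel,
                          threshold = thr),
            flags = if (inherits(stack, "registered_stack")) stack$flags else character(tn),
            layers = layers)
}

#' Pseudo-color overlay of the live mask on a grayscale frame
#'
#' Tints mask pixels red at a fixed alpha over the grayscale frame - the
#' standard visual check that detected "live" area coincides with cells.
#'
#' @param frame Grayscale matrix (rescaled to `[0, 1]` for display).
#' @param mask Logical matrix of the same size.
#' @param alpha Tint strength in `[0, 1]`.
#' @param path Optional PNG output path.
#' @return `H x W x 3` RGB array, invisibly if written to `path`.
#' @export
render_overlay <- function(frame, mask, alpha = 0.45, path = NULL) {
  stopifnot(all(dim(frame) == dim(mask)))
  rng <- range(frame)
  g <- if (diff(rng) > 0) (frame - rng[1]) / diff(rng) else frame * 0
  m <- mask * 1
  rgb <- array(0, dim = c(dim(frame), 3))
  rgb[, , 1] <- g * (1 - alpha * m) + alpha * m
  rgb[, , 2] <- g * (1 - alpha * m)
  rgb[, , 3] <- g * (1 - alpha * m)
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}
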