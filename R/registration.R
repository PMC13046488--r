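#' Estimate the translational shift between two frames
#'
#' Phase/cross-correlation: both frames are Hann-windowed and
#' mean-subtracted, the cross-power spectrum is inverted to find the
#' integer-pixel correlation peak, and the peak is refined on an upsampled
#' local DFT grid (subpixel accuracy well under 0.1 px on clean input).
#'
#' The returned `(dy, dx)` is the displacement frame `b` has undergone
#' relative to `a`: `b(i, j) ~ a(i - dy, j - dx)`. To align `b` onto `a`,
#' apply the negated shift (see [apply_shift()]).
#'
#' @param a,b Equal-size numeric matrices.
#' @param upsample Subpixel refinement factor (grid step `1/upsample` px).
#' @return Numeric `c(dy, dx)`. A zero-variance frame yields `c(0, 0)` with
#'   attribute `flag = "constant"` and a warning.
#' @export
estimate_shift <- function(a, b, upsample = 20) {
  stopifnot(all(dim(a) == dim(b)))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant frame: shift undefined, returning (0, 0)")
    return(structure(c(0, 0), flag = "constant"))
  }
  h <- nrow(a); w <- ncol(a)
  # integer peak from the unwindowed cross-correlation: a taper's
  # self-correlation would dominate and mask large displacements
  A0 <- stats::fft(a - mean(a))
  B0 <- stats::fft(b - mean(b))
  cc <- Re(stats::fft(Conj(A0) * B0, inverse = TRUE))
  p <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sy <- unwrap_freq(p[1] - 1, h)
  sx <- unwrap_freq(p[2] - 1, w)
  # subpixel refinement on the Hann-windowed spectrum (suppresses the
  # wrap-around edge discontinuity that biases fractional estimates)
  win <- outer(hann_window(h), hann_window(w))
  aw <- a * win; bw <- b * win
  A <- stats::fft(aw - mean(aw))
  B <- stats::fft(bw - mean(bw))
  R <- Conj(A) * B
  if (upsample > 1) {
    ys <- sy + seq(-1.2, 1.2, by = 1 / upsample)
    xs <- sx + seq(-1.2, 1.2, by = 1 / upsample)
    Ey <- exp(2i * pi * outer(ys, signed_freqs(h)) / h)
    Ex <- exp(2i * pi * outer(signed_freqs(w), xs) / w)
    U <- Re(Ey %*% R %*% Ex)
    q <- which(U == max(U), arr.ind = TRUE)[1, ]
    sy <- ys[q[1]]; sx <- xs[q[2]]
  }
  c(dy = unname(sy), dx = unname(sx))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
signed_freqs <- function(n) { k <- 0:(n - 1); ifelse(k > n / 2, k - n, k) }
unwrap_freq <- function(k, n) if (k > n / 2) k - n else k

#' Translate a frame by a (sub)pixel shift
#'
#' Returns `g` with `g(i, j) = frame(i - dy, j - dx)` (content moves by
#' `+dy, +dx`). Subpixel shifts use bilinear interpolation; out-of-frame
#' samples replicate the nearest edge so later background subtraction sees
#' no artificial dark border. Shifts below 1e-3 px return the frame
#' untouched.
#'
#' @param frame Numeric matrix.
#' @param dy,dx Shift in rows/columns (may be fractional).
#' @return Shifted matrix.
#' @export
apply_shift <- function(frame, dy, dx) {
  if (abs(dy) < 1e-3 && abs(dx) < 1e-3) return(frame)
  h <- nrow(frame); w <- ncol(frame)
  ry <- seq_len(h) - dy
  i0 <- floor(ry); wy <- ry - i0
  lo <- pmin(pmax(i0, 1), h); hi <- pmin(pmax(i0 + 1, 1), h)
  out <- frame[lo, , drop = FALSE] * (1 - wy) + frame[hi, , drop = FALSE] * wy
  rx <- seq_len(w) - dx
  j0 <- floor(rx); wx <- rx - j0
  lo <- pmin(pmax(j0, 1), w); hi <- pmin(pmax(j0 + 1, 1), w)
  t(t(out[, lo, drop = FALSE]) * (1 - wx) + t(out[, hi, drop = FALSE]) * wx)
}

#' Register a frame stack against translational drift
#'
#' Estimates a per-frame `(dy, dx)` displacement relative to the reference
#' frame and shifts every frame back, correcting stage drift and vibration
#' before motion analysis. In `"chain"` mode (default) each frame is
#' estimated against its predecessor and shifts accumulate, which stays
#' robust when well content changes slowly over a long time lapse;
#' `"reference"` mode estimates each frame directly against the reference.
#'
#' @param stack A `frame_stack` with at least 2 frames.
#' @param config [acq_config()]; uses `reg_mode`, `subpixel`, `max_shift`.
#' @param reference_index 0-based index of the reference frame (default 0).
#' @return A `registered_stack`: the stack plus `shifts` (a `T x 2` matrix
#'   of displacements relative to the reference; the reference row is 0)
#'   and per-frame QC `flags` (`"constant"` frames, `"max_shift"`
#'   exceedances).
#' @export
register_stack <- function(stack, config = acq_config(), reference_index = 0L) {
  stopifnot(inherits(stack, "frame_stack"))
  fr <- stack$frames
  tn <- dim(fr)[3]
  if (tn < 2) stop("registration needs at least 2 frames")
  ref <- reference_index + 1L
  shifts <- matrix(0, tn, 2, dimnames = list(NULL, c("dy", "dx")))
  flags <- character(tn)

  if (config$reg_mode == "chain") {
    step <- matrix(0, tn, 2)
    for (t in 2:tn) {
      s <- estimate_shift(fr[, , t - 1], fr[, , t])
      if (identical(attr(s, "flag"), "constant")) flags[t] <- "constant"
      step[t, ] <- s
    }
    # stage drift is smooth while jitter-induced misestimates are isolated:
    # median-filter the step series, then drop sub-deadband remnants
    if (tn >= 6) step[-1, ] <- apply(step[-1, , drop = FALSE], 2,
                                     function(v) stats::runmed(v, 5))
    step[abs(step) < config$reg_deadband] <- 0
    cum <- apply(step, 2, cumsum)
    shifts[] <- sweep(cum, 2, cum[ref, ])  # zero at the reference frame
  } else {
    for (t in seq_len(tn)) {
      if (t == ref) next
      s <- estimate_shift(fr[, , ref], fr[, , t])
      if (identical(attr(s, "flag"), "constant")) flags[t] <- "constant"
      s[abs(s) < config$reg_deadband] <- 0
      shifts[t, ] <- s
    }
  }

  too_big <- abs(shifts) > config$max_shift
  if (any(too_big)) {
    idx <- unique(which(too_big, arr.ind = TRUE)[, 1])
    flags[idx] <- paste0(flags[idx], ifelse(nzchar(flags[idx]), "+", ""), "max_shift")
  }
  if (!config$subpixel) shifts <- round(shifts)
  # near-integer shifts are applied as exact pixel moves: gratuitous
  # bilinear resampling attenuates the 1-px membrane crescents the motion
  # signal is built from
  near <- abs(shifts - round(shifts)) < 0.2
  shifts[near] <- round(shifts[near])

  aligned <- fr
  for (t in seq_len(tn)) {
    aligned[, , t] <- apply_shift(fr[, , t], -shifts[t, 1], -shifts[t, 2])
  }
  structure(list(frames = aligned, timestamps = stack$timestamps,
                 well = stack$well, shifts = shifts,
                 reference_index = as.integer(reference_index),
                 flags = flags),
            class = c("registered_stack", "frame_stack"))
}

#' Per-frame shift table of a registered stack
#'
#' @param rstack A `registered_stack`.
#' @return Tibble `(frame, dy_px, dx_px, flag)`; `frame` is 0-based.
#' @export
shift_table <- function(rstack) {
  stopifnot(inherits(rstack, "registered_stack"))
  tibble(frame = seq_len(nrow(rstack$shifts)) - 1L,
         dy_px = rstack$shifts[, 1], dx_px = rstack$shifts[, 2],
         flag = rstack$flags)
}
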