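# Shared fixtures and independent oracles.

# reduced-scale analysis configuration matching the default synthetic scene
test_config <- function(...) {
  defaults <- list(frame_height = 256, frame_width = 256,
                   total_duration = 23.5, cell_radius = 6,
                   background_radius = 40)
  args <- utils::modifyList(defaults, list(...))
  do.call(acq_config, args)
}

# single-drug layout: vehicle wells + 5 doses (1:5 from 8 nM) in duplicate
single_drug_layout <- function(doses = 8 * 5^(0:4), drug = "drugX",
                               sample = "S1", n_controls = 2) {
  nd <- length(doses)
  plate_layout(tibble::tibble(
    well = c(sprintf("A%02d", seq_len(n_controls)),
             paste0("B", sprintf("%02d", seq_len(nd))),
             paste0("C", sprintf("%02d", seq_len(nd)))),
    role = c(rep("vehicle_control", n_controls), rep("treatment", 2 * nd)),
    drug = c(rep(NA, n_controls), rep(drug, 2 * nd)),
    concentration_nM = c(rep(NA, n_controls), doses, doses),
    replicate = c(seq_len(n_controls), rep(1L, nd), rep(2L, nd)),
    sample = sample))
}

# plain raw-trace tibble for normalization tests (frames W..n, 0-based)
synthetic_raw_trace <- function(raw, W = 6, interval = 30) {
  tibble::tibble(frame = seq_along(raw) + W - 1L,
                 time_min = (seq_along(raw) + W - 1L) * interval,
                 raw_area_px = raw)
}

# assemble a plate-level raw trace table from per-well vectors
plate_raw_traces <- function(well_values, W = 6, interval = 30) {
  dplyr::bind_rows(lapply(names(well_values), function(wname) {
    synthetic_raw_trace(well_values[[wname]], W, interval) |>
      dplyr::mutate(well = wname)
  }))
}

# --- independent oracles -------------------------------------------------

# brute-force trailing per-pixel max (triple loop)
bf_running_max <- function(frames, W) {
  tn <- dim(frames)[3]
  out <- array(NA_real_, dim = dim(frames))
  for (t in W:tn) {
    for (i in seq_len(dim(frames)[1])) {
      for (j in seq_len(dim(frames)[2])) {
        out[i, j, t] <- max(frames[i, j, (t - W + 1):t])
      }
    }
  }
  out
}

# brute-force grayscale opening (erode then dilate, double loop) over the
# same disc footprint the implementation's brush uses
bf_opening <- function(x, radius) {
  h <- nrow(x); w <- ncol(x)
  br <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  offs <- which(br > 0, arr.ind = TRUE)
  offs <- data.frame(dy = offs[, 1] - radius - 1L, dx = offs[, 2] - radius - 1L)
  ero <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ys <- i + offs$dy; xs <- j + offs$dx
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    ero[i, j] <- min(x[cbind(ys[ok], xs[ok])])
  }
  dil <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ys <- i + offs$dy; xs <- j + offs$dx
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    dil[i, j] <- max(ero[cbind(ys[ok], xs[ok])])
  }
  dil
}

# exhaustive integer-shift cross-correlation (oracle for estimate_shift)
bf_best_integer_shift <- function(a, b, max_shift = 5) {
  best <- c(0, 0); best_score <- -Inf
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    bs <- apply_shift(b, -dy, -dx)   # undo candidate shift
    score <- sum(a * bs)
    if (score > best_score) { best_score <- score; best <- c(dy, dx) }
  }
  best
}

# circular roll (periodic shift) of a matrix
roll2 <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# set-comprehension oracle for the drug-library triage
bf_triage <- function(activity, threshold_nM) {
  drugs <- unique(activity$drug)
  res <- lapply(drugs, function(d) {
    v <- activity$min_active_nM[activity$drug == d]
    v[is.na(v)] <- Inf
    cat_d <- if (all(is.infinite(v))) "discarded_inactive"
    else if (any(v <= threshold_nM)) "preselected"
    else "discarded_weak"
    tibble::tibble(drug = d, category = cat_d)
  })
  dplyr::bind_rows(res)
}

# textured smooth test image (for registration tests)
smooth_random_image <- function(n = 96, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * n), n, n)
    EBImage::gblur(x, sigma = 3)
  })
}

# LD50 of a bare (dose, viability) curve via a one-time-point surface pair
ld50_curve_helper <- function(doses, viab) {
  df <- dplyr::bind_rows(
    tibble::tibble(sample = "S", drug = "D", dose_nM = doses,
                   frame = 6L, time_min = 180, viability = 100,
                   spread = 0, n_rep = 2L, single_replicate = FALSE),
    tibble::tibble(sample = "S", drug = "D", dose_nM = doses,
                   frame = 12L, time_min = 360, viability = viab,
                   spread = 0, n_rep = 2L, single_replicate = FALSE))
  s <- structure(df, class = c("dose_surface", class(tibble::tibble())))
  ld50(s)$ld50_nM
}
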