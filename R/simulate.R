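#' Synthetic scene configuration
#'
#' Describes one simulated well: non-adherent blasts rendered as bright
#' discs outlined by a dark membrane ring (the lens-like phase-contrast
#' appearance), live-cell membrane wobble, sparse large motile stromal
#' cells that can drag neighbouring blasts, stage drift, an illumination
#' gradient and sensor noise. The default geometry is the reduced test
#' scale (256 x 256 px, 48 frames at 30-min spacing); the full acquisition
#' scale (2,048 x 1,536, 192 frames) is obtained by setting `width`,
#' `height` and `n_frames` accordingly.
#'
#' `n_stroma = 2` scales the reference co-culture (100 stromal cells per
#' 4,000 blasts per well, a 1:40 ratio) to the default 100-blast scene.
#'
#' @param n_live,n_dead Blast counts (dead cells are static from frame 0).
#' @param cell_radius Blast radius, px.
#' @param ring_width Dark membrane ring width, px.
#' @param n_stroma Stromal cell count.
#' @param stroma_size Stromal major semi-axis, px (minor is 40\% of it).
#' @param jitter_amplitude Typical radial membrane excursion of a live
#'   blast per frame, px. Realised as fresh low-order Fourier modes of the
#'   ring boundary each frame; positions stay fixed (the collagen matrix
#'   holds cells in place), so only membranes move.
#' @param drift Stage drift `c(dy, dx)` in px per frame.
#' @param illumination_gradient Amplitude of a corner-to-corner linear
#'   shading ramp, intensity units.
#' @param noise_sigma Gaussian sensor noise SD, intensity units.
#' @param width,height,n_frames,frame_interval Geometry and sampling.
#' @param stroma_step Stromal random-walk step SD, px per frame.
#' @param drag_fraction Fraction of a stromal step imparted to a contacted
#'   blast.
#' @param background_level,cell_brightness,ring_depth,stroma_brightness
#'   Rendering intensity levels in `[0, 1]`.
#' @param seed Integer; fully determines the rendered stack.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_live = 100, n_dead = 0, cell_radius = 6,
                         ring_width = 2, n_stroma = 2, stroma_size = 12,
                         jitter_amplitude = 1, drift = c(0, 0),
                         illumination_gradient = 0.08, noise_sigma = 0.02,
                         width = 256, height = 256, n_frames = 48,
                         frame_interval = 30, stroma_step = 1.5,
                         drag_fraction = 0.5, background_level = 0.35,
                         cell_brightness = 0.85, ring_depth = 0.25,
                         stroma_brightness = 0.75, seed = 1L) {
  stopifnot(n_live >= 0, n_dead >= 0, n_stroma >= 0,
            jitter_amplitude >= 0, cell_radius > 0, n_frames >= 2)
  structure(as.list(environment()), class = "scene_config")
}

#' Dose-dependent kill model
#'
#' Ground-truth drug action: each live cell dies at an exponential time
#' whose hazard follows a Hill function of concentration,
#' `hazard(c) = baseline + max_hazard * c^s / (c^s + c50^s)` per hour.
#' The default `max_hazard = 2 log(2) / 20.5` makes the half-effect
#' concentration (`hazard = max_hazard / 2`) halve the population over
#' 20.5 h - the span between the 3-h baseline frame and the endpoint of
#' the default 48-frame scene - so the measured 50\% crossing sits at the
#' model's `c50` by construction.
#'
#' @param concentration Drug concentration, nM (0 = vehicle).
#' @param c50 True half-effect concentration, nM.
#' @param hill_slope Hill coefficient.
#' @param max_hazard Saturating kill hazard, per hour.
#' @param baseline_hazard Drug-independent death hazard, per hour.
#' @return A `kill_model` list with the resolved `hazard`.
#' @export
kill_model <- function(concentration, c50 = 20, hill_slope = 1,
                       max_hazard = 2 * log(2) / 20.5, baseline_hazard = 0) {
  stopifnot(concentration >= 0, c50 > 0, max_hazard >= 0, baseline_hazard >= 0)
  cs <- concentration^hill_slope
  hazard <- baseline_hazard + max_hazard * cs / (cs + c50^hill_slope)
  structure(list(concentration = concentration, c50 = c50,
                 hill_slope = hill_slope, max_hazard = max_hazard,
                 baseline_hazard = baseline_hazard, hazard = hazard),
            class = "kill_model")
}

#' Simulate one well's time lapse with per-cell ground truth
#'
#' Renders the full stack described by [scene_config()]: background plus
#' illumination gradient, global stage drift, bright-disc/dark-ring blasts
#' whose boundaries wobble while alive and freeze at death, elongated
#' motile stromal cells that drag any blast within contact range (every
#' such contact is logged), and additive Gaussian noise. Output is fully
#' determined by the scene seed.
#'
#' @param scene A `scene_config`.
#' @param kill A [kill_model()] or `NULL` (vehicle; nothing dies unless
#'   the baseline hazard is positive).
#' @return A list of class `synthetic_well`:
#'   * `stack` - the rendered `frame_stack`;
#'   * `truth` - `cells` (id, type, position, radius, death hour),
#'     `per_frame` (0-based frame, time, true alive count and live pixel
#'     area), `displacements` (stroma-contact log), and the applied
#'     `drift`.
#' @export
simulate_well <- function(scene, kill = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  withr::with_seed(as.integer(scene$seed) %% .Machine$integer.max, {
    simulate_well_impl(scene, kill)
  })
}

simulate_well_impl <- function(scene, kill) {
  h <- scene$height; w <- scene$width; tn <- scene$n_frames
  r <- scene$cell_radius
  n_cells <- scene$n_live + scene$n_dead
  cell_area <- pi * r^2
  stroma_area <- pi * scene$stroma_size * (0.4 * scene$stroma_size)
  if (n_cells * cell_area + scene$n_stroma * stroma_area > 0.6 * h * w) {
    stop("overcrowded scene: requested cell area exceeds 60% of the frame")
  }
  times_h <- (seq_len(tn) - 1) * scene$frame_interval / 60

  # placement: non-overlapping centres away from the border (the border
  # strip doubles as the pipeline's noise-floor region)
  total_drift <- abs(scene$drift) * tn
  margin <- 2 * r + 8 + min(10, ceiling(max(total_drift)))
  if (2 * margin >= min(h, w)) stop("frame too small for the margin")
  pos <- place_cells(n_cells, h, w, margin, min_sep = 2.2 * r)

  type <- c(rep("blast_live", scene$n_live), rep("blast_dead", scene$n_dead))
  death_h <- rep(Inf, n_cells)
  if (scene$n_dead > 0) death_h[type == "blast_dead"] <- 0
  hazard <- if (!is.null(kill)) kill$hazard else 0
  if (hazard > 0 && scene$n_live > 0) {
    death_h[type == "blast_live"] <- rexp(scene$n_live, rate = hazard)
  }

  # sensor noise drawn before any per-cell stream so that scenes differing
  # only in appended cells share identical noise fields
  noise <- array(rnorm(h * w * tn, sd = scene$noise_sigma), dim = c(h, w, tn))

  # stroma tracks: reflected random walk
  ns <- scene$n_stroma
  s_pos <- NULL; s_theta <- NULL; s_steps <- NULL
  if (ns > 0) {
    sm <- scene$stroma_size + 4
    s_pos <- cbind(runif(ns, sm, h - sm), runif(ns, sm, w - sm))
    s_theta <- runif(ns, 0, pi)
    s_steps <- array(rnorm(ns * 2 * tn, sd = scene$stroma_step),
                     dim = c(ns, 2, tn))
    s_steps[, , 1] <- 0
  }

  # membrane boundary modes: 6 Fourier coefficients per cell per frame,
  # drawn cell by cell (appending cells never reshuffles earlier cells'
  # draws), frozen from the first frame at which the cell is dead
  jit_sd <- scene$jitter_amplitude / sqrt(3)
  coefs <- array(0, dim = c(n_cells, 6, tn))
  alive_frames <- vapply(death_h, function(d) sum(times_h < d), 0L)
  for (i in seq_len(n_cells)) {
    coefs[i, , ] <- rnorm(6 * tn, sd = jit_sd)
    fa <- alive_frames[i]
    if (fa < tn) {
      frozen <- coefs[i, , max(fa, 1L)]
      for (t in (fa + 1):tn) coefs[i, , t] <- frozen
    }
  }

  grad <- scene$illumination_gradient *
    (outer(seq_len(h) / h, rep(1, w)) + outer(rep(1, h), seq_len(w) / w)) / 2
  base <- scene$background_level + grad

  frames <- array(0, dim = c(h, w, tn))
  drag <- matrix(0, n_cells, 2)
  disp_log <- list()

  for (t in seq_len(tn)) {
    drift_off <- scene$drift * (t - 1)
    img <- base
    if (ns > 0) {
      if (t > 1) {
        for (s in seq_len(ns)) {
          step <- s_steps[s, , t]
          s_pos[s, ] <- reflect_into(s_pos[s, ] + step, h, w, scene$stroma_size + 4)
          s_theta[s] <- s_theta[s] + rnorm(1, sd = 0.05)
          # drag any blast inside the stroma's dilated elliptical footprint
          dyc <- pos[, 1] + drag[, 1] - s_pos[s, 1]
          dxc <- pos[, 2] + drag[, 2] - s_pos[s, 2]
          u <- cos(s_theta[s]) * dxc + sin(s_theta[s]) * dyc
          v <- -sin(s_theta[s]) * dxc + cos(s_theta[s]) * dyc
          ea <- scene$stroma_size + r
          eb <- 0.4 * scene$stroma_size + r
          hit <- which((u / ea)^2 + (v / eb)^2 < 1)
          if (length(hit)) {
            drag[hit, 1] <- drag[hit, 1] + scene$drag_fraction * step[1]
            drag[hit, 2] <- drag[hit, 2] + scene$drag_fraction * step[2]
            disp_log[[length(disp_log) + 1]] <-
              tibble(frame = t - 1L, stroma = s, cell = hit,
                     dy = scene$drag_fraction * step[1],
                     dx = scene$drag_fraction * step[2])
          }
        }
      }
      for (s in seq_len(ns)) {
        img <- draw_stroma(img, s_pos[s, 1] + drift_off[1],
                           s_pos[s, 2] + drift_off[2], scene$stroma_size,
                           0.4 * scene$stroma_size, s_theta[s],
                           scene$stroma_brightness)
      }
    }
    for (i in seq_len(n_cells)) {
      img <- draw_cell(img, pos[i, 1] + drag[i, 1] + drift_off[1],
                       pos[i, 2] + drag[i, 2] + drift_off[2], r,
                       scene$ring_width, coefs[i, , t],
                       scene$cell_brightness, scene$ring_depth)
    }
    img <- img + noise[, , t]
    img[img < 0] <- 0; img[img > 1] <- 1
    frames[, , t] <- img
  }

  n_alive <- vapply(times_h, function(tt) sum(death_h > tt), 0L)
  truth <- list(
    cells = tibble(cell = seq_len(n_cells), type = type,
                   y0 = pos[, 1], x0 = pos[, 2], radius = r,
                   death_h = death_h),
    per_frame = tibble(frame = seq_len(tn) - 1L,
                       time_min = (seq_len(tn) - 1) * scene$frame_interval,
                       n_alive = n_alive,
                       true_live_area_px = round(n_alive * cell_area)),
    displacements = if (length(disp_log)) dplyr::bind_rows(disp_log) else
      tibble(frame = integer(), stroma = integer(), cell = integer(),
             dy = numeric(), dx = numeric()),
    drift = scene$drift
  )
  stack <- frame_stack(frames, interval = scene$frame_interval)
  structure(list(stack = stack, truth = truth, scene = scene, kill = kill),
            class = "synthetic_well")
}

place_cells <- function(n, h, w, margin, min_sep, max_tries = 2000) {
  if (n == 0) return(matrix(numeric(), 0, 2))
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      p <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
      if (i == 1 || all((pos[seq_len(i - 1), 1] - p[1])^2 +
                          (pos[seq_len(i - 1), 2] - p[2])^2 >= min_sep^2)) {
        pos[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place ", n, " cells without overlap; ",
                      "scene is effectively overcrowded")
  }
  pos
}

reflect_into <- function(p, h, w, m) {
  lo <- c(m, m); hi <- c(h - m, w - m)
  for (k in 1:2) {
    if (p[k] < lo[k]) p[k] <- 2 * lo[k] - p[k]
    if (p[k] > hi[k]) p[k] <- 2 * hi[k] - p[k]
  }
  p
}

# bright cytoplasm disc with dark membrane ring; 1-px soft edges
draw_cell <- function(img, cy, cx, r, ring_w, coef, bright, dark) {
  h <- nrow(img); w <- ncol(img)
  pr <- ceiling(r + 3 + ring_w)
  ys <- max(1, floor(cy - pr)):min(h, ceiling(cy + pr))
  xs <- max(1, floor(cx - pr)):min(w, ceiling(cx + pr))
  if (!length(ys) || !length(xs)) return(img)
  dy <- ys - cy; dx <- xs - cx
  d <- sqrt(outer(dy^2, dx^2, `+`))
  th <- atan2(outer(dy, rep(1, length(dx))), outer(rep(1, length(dy)), dx))
  # modes k = 2..4 only: k = 1 would translate the whole cell, but the
  # collagen matrix pins positions and only the membrane deforms
  delta <- coef[1] * cos(2 * th) + coef[2] * cos(3 * th) + coef[3] * cos(4 * th) +
    coef[4] * sin(2 * th) + coef[5] * sin(3 * th) + coef[6] * sin(4 * th)
  delta <- pmin(pmax(delta, -r / 2), r / 2)
  rr <- r + delta
  a_cyto <- pmin(pmax(rr - ring_w + 0.5 - d, 0), 1)
  a_cell <- pmin(pmax(rr + 0.5 - d, 0), 1)
  patch <- img[ys, xs]
  img[ys, xs] <- a_cyto * bright + (a_cell - a_cyto) * dark +
    (1 - a_cell) * patch
  img
}

draw_stroma <- function(img, cy, cx, a, b, theta, bright) {
  h <- nrow(img); w <- ncol(img)
  pr <- ceiling(a + 2)
  ys <- max(1, floor(cy - pr)):min(h, ceiling(cy + pr))
  xs <- max(1, floor(cx - pr)):min(w, ceiling(cx + pr))
  if (!length(ys) || !length(xs)) return(img)
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  e <- sqrt((u / a)^2 + (v / b)^2)
  cover <- pmin(pmax((1 - e) * b + 0.5, 0), 1)
  patch <- img[ys, xs]
  img[ys, xs] <- cover * bright + (1 - cover) * patch
  img
}

#' Ground-truth viability curve, normalized as the pipeline normalizes
#'
#' True alive fraction expressed as percent of the alive count at the
#' baseline frame `W`, directly comparable to `pct_baseline`.
#'
#' @param well A `synthetic_well`.
#' @param config [acq_config()] supplying the baseline frame index.
#' @return Tibble `(frame, time_min, n_alive, true_pct_baseline)` from
#'   frame `W` on.
#' @export
true_viability <- function(well, config = acq_config()) {
  pf <- well$truth$per_frame
  W <- config$motion_window
  base <- pf$n_alive[pf$frame == W]
  if (!length(base) || base == 0) stop("no live cells at the baseline frame")
  pf |>
    dplyr::filter(.data$frame >= W) |>
    dplyr::mutate(true_pct_baseline = 100 * .data$n_alive / base)
}

#' Simulate every well of a plate
#'
#' Vehicle-control wells receive no kill model; treatment and
#' positive-control wells receive the Hill kill model at their layout
#' concentration. Per-well RNG streams are derived from the master seed
#' and the well address, so the whole plate is reproducible from one
#' integer and wells are independent.
#'
#' @param layout A `plate_layout`.
#' @param scene A `scene_config` used for every well (its `seed` is
#'   replaced by the per-well sub-seed).
#' @param c50_true True half-effect concentration in nM; a single value or
#'   a named vector keyed by drug.
#' @param hill_slope,max_hazard,baseline_hazard Passed to [kill_model()].
#' @param seed Master seed.
#' @return A `synthetic_plate`: named lists `stacks` and `truth` (one
#'   entry per non-empty well) plus the `layout`.
#' @export
simulate_plate <- function(layout, scene = scene_config(), c50_true = 20,
                           hill_slope = 1, max_hazard = 2 * log(2) / 20.5,
                           baseline_hazard = 0, seed = 1L) {
  wells <- as_tibble(layout) |> dplyr::filter(.data$role != "empty")
  stacks <- list(); truths <- list()
  for (i in seq_len(nrow(wells))) {
    wi <- wells[i, ]
    sub_seed <- (as.numeric(seed) * 1000003 + wi$row * 24 + wi$col) %% 2147483647
    sc <- scene; sc$seed <- as.integer(sub_seed)
    kill <- NULL
    if (wi$role %in% c("treatment", "positive_control")) {
      c50 <- if (length(c50_true) > 1) {
        if (!wi$drug %in% names(c50_true)) stop("no c50_true for drug ", wi$drug)
        c50_true[[wi$drug]]
      } else c50_true
      kill <- kill_model(wi$concentration_nM, c50 = c50,
                         hill_slope = hill_slope, max_hazard = max_hazard,
                         baseline_hazard = baseline_hazard)
    } else if (baseline_hazard > 0) {
      kill <- kill_model(0, c50 = 1, max_hazard = 0,
                         baseline_hazard = baseline_hazard)
    }
    sim <- simulate_well(sc, kill)
    sim$stack$well <- wi
    stacks[[wi$well]] <- sim$stack
    truths[[wi$well]] <- sim$truth
  }
  structure(list(stacks = stacks, truth = truths, layout = layout,
                 seed = seed),
            class = "synthetic_plate")
}
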