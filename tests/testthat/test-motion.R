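test_that("background subtraction removes smooth illumination, keeps cells", {
  # uniform frame -> all zero
  expect_equal(subtract_background(matrix(0.4, 48, 48), radius = 8),
               matrix(0, 48, 48))
  expect_error(subtract_background(matrix(0, 4, 4), radius = 0), "radius")

  # ramp + bright discs: oracle is a brute-force grayscale opening
  withr::with_seed(5, {
    n <- 64
    ramp <- outer(seq(0, 0.2, length.out = n), rep(1, n))
    img <- 0.3 + ramp
    centres <- cbind(c(16, 40, 52), c(20, 44, 12))
    for (k in 1:3) {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if ((i - centres[k, 1])^2 + (j - centres[k, 2])^2 <= 25) {
          img[i, j] <- img[i, j] + 0.4
        }
      }
    }
  })
  out <- subtract_background(img, radius = 8)
  oracle <- img - bf_opening(img, 8)
  oracle[oracle < 0] <- 0
  core <- 10:54  # away from the border, where padding conventions differ
  expect_lt(max(abs(out[core, core] - oracle[core, core])), 1e-6)

  disc <- (outer((1:64 - 16)^2, rep(1, 64), `+`) +
             outer(rep(1, 64), (1:64 - 20)^2) - (1:64 - 16)^2) <= 25
  # discs retain >= 80% of their contrast
  expect_gt(mean(out[centres[1, 1], centres[1, 2]]), 0.8 * 0.4)
  # ramp residual < 5% of ramp amplitude away from discs
  expect_lt(stats::quantile(out[1:8, 30:64], 0.99), 0.05 * 0.2)

  # near-idempotence on a background-free frame
  out2 <- subtract_background(out, radius = 8)
  cell_px <- out > 0.3
  expect_lt(max(abs(out2[cell_px] - out[cell_px]) / out[cell_px]), 0.1)
})

test_that("running max equals the brute-force trailing-window oracle", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      tn <- sample(6:12, 1); W <- sample(2:5, 1)
      fr <- array(runif(4 * 4 * tn), dim = c(4, 4, tn))
      expect_equal(running_max(fr, W)[, , W:tn], bf_running_max(fr, W)[, , W:tn])
    }
  })
  expect_error(running_max(array(0, c(2, 2, 5)), W = 1), "W must be >= 2")
  expect_error(running_max(array(0, c(2, 2, 3)), W = 6), "at least")
  # constant stack -> identical constant frames
  const <- array(0.7, dim = c(3, 3, 8))
  expect_equal(running_max(const, 6)[, , 6:8], const[, , 6:8])
})

test_that("motion difference is bright only where intensity left a pixel", {
  a <- matrix(runif(64), 8, 8)
  expect_equal(motion_difference(a, a), matrix(0, 8, 8))

  # jittered disc: ring where the disc was, interior cancels
  disc_at <- function(cy, cx) {
    outer((1:32 - cy)^2, (1:32 - cx)^2, `+`) <= 36
  }
  f1 <- 0.1 + 0.6 * disc_at(16, 16)
  f2 <- 0.1 + 0.6 * disc_at(16, 17)
  mp <- pmax(f1, f2)
  d <- motion_difference(mp, f2)
  ring <- disc_at(16, 16) & !disc_at(16, 17)
  interior <- disc_at(16, 16) & disc_at(16, 17)
  expect_true(all(d[ring] > 0.5))
  expect_equal(max(d[interior]), 0)
  # static disc: zero difference everywhere
  expect_equal(motion_difference(pmax(f1, f1), f1), matrix(0, 32, 32))
})

test_that("rings_to_spots fills rings into solid cell spots", {
  expect_equal(sum(rings_to_spots(matrix(0, 32, 32), sigma = 2)), 0)

  # ideal 10-px ring -> mask covers >= 90% of the enclosed disc
  n <- 48
  d2 <- outer((1:n - 24)^2, (1:n - 24)^2, `+`)
  ring <- (d2 >= 81 & d2 <= 121) * 0.8
  mask <- rings_to_spots(ring, sigma = 5, k_rel = 0.25, k_abs = 0.01)
  disc <- d2 <= 100
  expect_gte(sum(mask & disc) / sum(disc), 0.9)

  # two well-separated jittering cells -> two connected components
  two <- matrix(0, 96, 96)
  d2a <- outer((1:96 - 25)^2, (1:96 - 25)^2, `+`)
  d2b <- outer((1:96 - 70)^2, (1:96 - 70)^2, `+`)
  two[d2a >= 25 & d2a <= 49] <- 0.7
  two[d2b >= 25 & d2b <= 49] <- 0.7
  m2 <- rings_to_spots(two, sigma = 3, k_rel = 0.25, k_abs = 0.01)
  expect_equal(max(EBImage::bwlabel(m2)), 2)
})

test_that("static scenes yield near-zero live area; live scenes persist", {
  cfg <- test_config()
  # all-static: 60 dead cells, no stroma, no drift
  dead <- simulate_well(scene_config(n_live = 0, n_dead = 60, n_stroma = 0,
                                     seed = 101))
  vt_dead <- viability_trace(dead$stack, cfg)
  expect_lte(max(vt_dead$raw_area_px), 0.01 * 256 * 256)

  # live cells: stable signal, scaling with count
  live <- simulate_well(scene_config(n_live = 100, n_stroma = 0, seed = 102))
  vt_live <- viability_trace(live$stack, cfg)
  m <- median(vt_live$raw_area_px)
  expect_gt(m, 100 * pi * 36 * 0.5)  # at least half the true cell area
  expect_true(all(vt_live$raw_area_px > 0.8 * m &
                    vt_live$raw_area_px < 1.2 * m))
})

test_that("live area is invariant to global intensity scaling", {
  cfg <- test_config()
  sim <- simulate_well(scene_config(n_live = 40, n_stroma = 0, seed = 103))
  base <- viability_trace(sim$stack, cfg)$raw_area_px
  for (k in c(0.5, 2)) {
    scaled <- sim$stack
    scaled$frames <- scaled$frames * k
    vk <- viability_trace(scaled, cfg)$raw_area_px
    expect_lt(max(abs(vk - base) / base), 0.05)
  }
})

test_that("the max-object-area filter drops oversized components", {
  diff <- matrix(0, 64, 64)
  d2a <- outer((1:64 - 16)^2, (1:64 - 16)^2, `+`)
  d2b <- outer((1:64 - 45)^2, (1:64 - 45)^2, `+`)
  diff[d2a <= 16] <- 0.8       # small spot
  diff[d2b <= 144] <- 0.8      # big spot
  m_all <- rings_to_spots(diff, sigma = 1, k_rel = 0.25, k_abs = 0.01)
  m_cut <- rings_to_spots(diff, sigma = 1, k_rel = 0.25, k_abs = 0.01,
                          max_object_area = 200)
  expect_equal(max(EBImage::bwlabel(m_all)), 2)
  expect_equal(max(EBImage::bwlabel(m_cut)), 1)
})

test_that("overlays tint exactly the masked pixels red", {
  fr <- matrix(runif(64), 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[3:4, 5:6] <- TRUE
  rgb <- render_overlay(fr, mask, alpha = 0.5)
  expect_equal(dim(rgb), c(8, 8, 3))
  expect_true(all(rgb[, , 1][mask] > rgb[, , 2][mask]))
  off <- !mask
  expect_equal(rgb[, , 1][off], rgb[, , 2][off])
  f <- withr::local_tempfile(fileext = ".png")
  render_overlay(fr, mask, path = f)
  expect_true(file.exists(f))
})
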