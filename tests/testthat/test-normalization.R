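test_that("baseline normalization pins frame W at exactly 100%", {
  cfg <- acq_config()
  tr <- synthetic_raw_trace(c(40000, 30000, 20000, 10000))
  out <- normalize_within_well(tr, cfg)
  expect_identical(out$pct_baseline[1], 100)
  expect_equal(out$pct_baseline[4], 25)  # 10000 / 40000

  # constant trace stays at 100 everywhere
  flat <- normalize_within_well(synthetic_raw_trace(rep(5000, 6)), cfg)
  expect_true(all(flat$pct_baseline == 100))

  # scale invariance: multiplying raw areas by c > 0 changes nothing
  for (c_ in c(0.5, 3, 117)) {
    sc <- normalize_within_well(
      synthetic_raw_trace(c(40000, 30000, 20000, 10000) * c_), cfg)
    expect_equal(sc$pct_baseline, out$pct_baseline)
  }

  # zero baseline flags static start
  z <- normalize_within_well(synthetic_raw_trace(c(0, 10, 20)), cfg)
  expect_true(attr(z, "static_start"))
  expect_true(all(is.na(z$pct_baseline)))
})

test_that("control normalization divides by the control mean per time", {
  cfg <- acq_config()
  well <- normalize_within_well(synthetic_raw_trace(c(100, 40, 20)), cfg)
  ctrl <- lapply(c(1, 1.5), function(k) {
    normalize_within_well(synthetic_raw_trace(c(100, 80, 80) * k), cfg)
  })
  out <- normalize_to_control(well, ctrl)
  expect_equal(out$pct_control, c(100, 50, 25))  # 40/80, 20/80
  expect_error(normalize_to_control(well, ctrl[1]), "at least 2")
})

test_that("the mean of normalized controls is exactly 100% at every time", {
  withr::with_seed(21, {
    raws <- lapply(1:10, function(i) runif(20, 1000, 50000))
  })
  traces <- plate_raw_traces(setNames(raws, sprintf("A%02d", 1:10)))
  lay <- plate_layout(tibble::tibble(
    well = c(sprintf("A%02d", 1:10), "B01"),
    role = c(rep("vehicle_control", 10), "treatment"),
    drug = c(rep(NA, 10), "D"),
    concentration_nM = c(rep(NA, 10), 100),
    replicate = 1L, sample = "S1"))
  traces <- dplyr::bind_rows(traces,
                             synthetic_raw_trace(runif(20, 1000, 50000)) |>
                               dplyr::mutate(well = "B01"))
  norm <- normalize_traces(traces, lay, acq_config())
  ctrl_mean <- norm |>
    dplyr::filter(role == "vehicle_control") |>
    dplyr::group_by(frame) |>
    dplyr::summarise(m = mean(pct_control))
  expect_equal(ctrl_mean$m, rep(100, 20))
})

test_that("static-start wells are flagged and kept out of control means", {
  lay <- plate_layout(tibble::tibble(
    well = c("A01", "A02", "A03", "B01"),
    role = c(rep("vehicle_control", 3), "treatment"),
    drug = c(NA, NA, NA, "D"),
    concentration_nM = c(NA, NA, NA, 100),
    replicate = 1L, sample = "S1"))
  traces <- plate_raw_traces(list(
    A01 = c(10000, 9000, 8000), A02 = c(12000, 11000, 10000),
    A03 = c(100, 90, 80),        # < 5% of median control baseline
    B01 = c(9000, 5000, 2000)))
  norm <- normalize_traces(traces, lay, acq_config())
  expect_true(all(norm$static_start[norm$well == "A03"]))
  expect_false(any(norm$static_start[norm$well %in% c("A01", "A02")]))
  # control mean built from the two viable controls only
  b_end <- norm |> dplyr::filter(well == "B01", frame == 8)
  ctrl_mean <- mean(c(100 * 8000 / 10000, 100 * 10000 / 12000))
  expect_equal(b_end$pct_control, 100 * (100 * 2000 / 9000) / ctrl_mean)
})

test_that("QC verdicts follow the control-viability thresholds", {
  lay <- single_drug_layout()
  cfg <- acq_config(qc_time = 60)
  mk_norm <- function(endpoint_pct) {
    # two control wells decaying to the stated percentage at 60 h (frame 120)
    vals <- function(p) c(seq(100, p, length.out = 115), rep(p, 76))
    traces <- plate_raw_traces(list(A01 = vals(endpoint_pct) * 100,
                                    A02 = vals(endpoint_pct) * 100))
    normalize_traces(traces, lay, cfg)
  }
  expect_identical(evaluate_qc(mk_norm(65), lay, cfg)$samples$verdict, "valid")
  expect_identical(evaluate_qc(mk_norm(45), lay, cfg)$samples$verdict, "invalid")

  # conditional band: needs a confirming dose-response pattern
  norm55 <- mk_norm(55)
  expect_identical(evaluate_qc(norm55, lay, cfg)$samples$verdict, "invalid")
  doses <- 8 * 5^(0:4)
  surf <- structure(
    tidyr::crossing(tibble::tibble(sample = "S1", drug = "drugX"),
                    dose_nM = doses,
                    tibble::tibble(frame = c(6L, 192L),
                                   time_min = c(180, 5760))) |>
      dplyr::mutate(viability = dplyr::if_else(
        frame == 6L, 100, 100 - 18 * log10(dose_nM)),
        spread = 0, n_rep = 2L, single_replicate = FALSE),
    class = c("dose_surface", class(tibble::tibble())))
  expect_identical(evaluate_qc(norm55, lay, cfg, surfaces = surf)$samples$verdict,
                   "conditional_valid")

  # monotone: raising control viability never worsens the verdict
  ranks <- c(invalid = 0, conditional_valid = 1, valid = 2)
  verdicts <- vapply(c(45, 52, 61, 80), function(p) {
    evaluate_qc(mk_norm(p), lay, cfg, surfaces = surf)$samples$verdict
  }, "")
  expect_true(all(diff(ranks[verdicts]) >= 0))
})

test_that("all-static controls invalidate the sample outright", {
  lay <- single_drug_layout()
  traces <- plate_raw_traces(list(A01 = rep(0, 10), A02 = rep(0, 10)))
  norm <- normalize_traces(traces, lay, acq_config())
  rep_ <- evaluate_qc(norm, lay, acq_config())
  expect_identical(rep_$samples$verdict, "invalid")
  expect_match(rep_$samples$reason, "non-viable at start")
})

test_that("exclusion rate matches screen bookkeeping", {
  expect_equal(round(triage_exclusion_rate(31, 6)), 19)
  expect_equal(triage_exclusion_rate(31, 0), 0)
  expect_equal(triage_exclusion_rate(31, 31), 100)
  expect_error(triage_exclusion_rate(0, 0))
  expect_error(triage_exclusion_rate(5, 6))
})
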