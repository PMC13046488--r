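make_surface <- function(doses, times_min, viab_fun, sample = "S1",
                         drug = "D") {
  df <- tidyr::crossing(dose_nM = doses, time_min = times_min) |>
    dplyr::mutate(sample = sample, drug = drug,
                  frame = as.integer(time_min / 30),
                  viability = mapply(viab_fun, dose_nM, time_min),
                  spread = 0, n_rep = 2L, single_replicate = FALSE)
  structure(df, class = c("dose_surface", class(tibble::tibble())))
}

test_that("build_surface averages replicates and guards roles", {
  lay <- single_drug_layout(doses = c(10, 50))
  norm <- tibble::tibble(
    well = c("B01", "C01", "B02", "C02"),
    role = "treatment", drug = "drugX",
    concentration_nM = c(10, 10, 50, 50), replicate = c(1L, 2L, 1L, 2L),
    sample = "S1", frame = 6L, time_min = 180,
    pct_baseline = 100, pct_control = c(60, 80, 30, 50),
    static_start = FALSE)
  surf <- build_surface(norm, lay)
  expect_equal(surf$viability, c(70, 40))
  expect_equal(surf$spread, c(20, 20))
  expect_false(any(surf$single_replicate))
  expect_length(attr(surf, "incomplete"), 0)

  # vehicle-only input is rejected
  veh <- dplyr::mutate(norm, role = "vehicle_control")
  expect_error(build_surface(veh), "treatment")

  # missing dose flags the drug incomplete; lone replicate flagged
  surf2 <- build_surface(norm[c(1, 3), ], lay)
  expect_true(all(surf2$single_replicate))
  partial <- build_surface(norm[norm$concentration_nM == 10, ], lay)
  expect_identical(attr(partial, "incomplete"), "drugX")
})

test_that("ld50 interpolates in log dose and censors at the range", {
  doses <- c(8, 40, 200, 1000, 5000)
  # censored: viability above 50% even at the top dose
  s_cens <- make_surface(doses, c(180, 360),
                         function(d, t) 100 - 5 * log10(d))
  r <- ld50(s_cens)
  expect_equal(r$ld50_nM, 10000)
  expect_true(r$ld50_censored)

  # exact 50% at a tested dose
  v50 <- c(90, 70, 50, 30, 10)
  s_exact <- make_surface(doses, c(180, 360),
                          function(d, t) v50[match(d, doses)])
  r2 <- ld50(s_exact)
  expect_equal(r2$ld50_nM, 200)
  expect_false(r2$ld50_censored)

  # log10-linear interpolation: 80% at 10 nM, 20% at 50 nM -> 10^1.349
  s_int <- make_surface(c(10, 50), c(180, 360),
                        function(d, t) if (d == 10) 80 else 20)
  expect_equal(ld50(s_int)$ld50_nM,
               10^(1 + 0.5 * (log10(50) - 1)), tolerance = 1e-10)

  # below range: under 50% already at the lowest dose
  s_low <- make_surface(doses, c(180, 360), function(d, t) 20)
  r3 <- ld50(s_low)
  expect_equal(r3$ld50_nM, 8)
  expect_true(r3$below_range)

  # non-monotone: lowest-dose crossing used, flagged
  vnm <- c(80, 30, 70, 30, 10)
  s_nm <- make_surface(doses, c(180, 360),
                       function(d, t) vnm[match(d, doses)])
  r4 <- ld50(s_nm)
  expect_true(r4$nonmonotone)
  expect_lt(r4$ld50_nM, 40)
})

test_that("ld50 is monotone under pointwise viability lowering", {
  doses <- c(8, 40, 200, 1000, 5000)
  withr::with_seed(31, {
    for (i in 1:20) {
      v <- sort(runif(5, 5, 120), decreasing = TRUE)
      drop <- runif(5, 0, 20)
      r_hi <- ld50_curve_helper(doses, v)
      r_lo <- ld50_curve_helper(doses, pmax(v - drop, 0))
      expect_lte(r_lo, r_hi)
    }
  })
})

test_that("censoring flag and value are consistent", {
  doses <- c(10, 100, 1000)
  withr::with_seed(32, {
    for (i in 1:25) {
      v <- runif(3, 0, 130)
      s <- make_surface(doses, c(180, 360),
                        function(d, t) v[match(d, doses)])
      r <- ld50(s)
      expect_identical(r$ld50_censored, r$ld50_nM == 2 * max(doses))
    }
  })
})

test_that("auc integrates viability over time, normalized to [0, 1]", {
  doses <- c(10, 100)
  times <- seq(180, 1440, by = 90)
  expect_equal(auc(make_surface(doses, times, function(d, t) 100))$auc, 1)
  expect_equal(auc(make_surface(doses, times, function(d, t) 0))$auc, 0)

  # linear decay 100 -> 0 over the run: closed form 0.5, oracle via trapz
  lin <- function(d, t) 100 * (max(times) - t) / (max(times) - min(times))
  s_lin <- make_surface(doses, times, lin)
  expect_equal(auc(s_lin)$auc, 0.5, tolerance = 1e-10)
  oracle <- pracma::trapz(times, sapply(times, lin, d = 10) / 100) /
    (max(times) - min(times))
  expect_equal(auc(s_lin)$auc, oracle)

  # single time point is an error
  expect_error(auc(make_surface(doses, 180, function(d, t) 50)), "single time")

  # monotone: lowering viability never raises the AUC
  s_half <- make_surface(doses, times, function(d, t) lin(d, t) / 2)
  expect_lt(auc(s_half)$auc, auc(s_lin)$auc)
})

test_that("triage splits the library into three exact sets", {
  # reference screen: 166 drugs, 57 inactive everywhere, 49 only above
  # 0.5 uM, 60 preselected
  withr::with_seed(41, {
    drugs <- sprintf("drug%03d", 1:166)
    cat_true <- rep(c("discarded_inactive", "discarded_weak", "preselected"),
                    c(57, 49, 60))
    rows <- lapply(seq_along(drugs), function(i) {
      conc <- switch(cat_true[i],
        discarded_inactive = rep(NA_real_, 8),
        discarded_weak = runif(8, 600, 5000),
        preselected = c(runif(1, 1, 500), runif(7, 1, 5000)))
      tibble::tibble(drug = drugs[i], sample = sprintf("P%d", 1:8),
                     min_active_nM = conc)
    })
    activity <- dplyr::bind_rows(rows)
  })
  res <- triage_panel(activity, threshold_nM = 500)
  counts <- attr(res, "counts")
  expect_equal(unname(counts["discarded_inactive"]), 57)
  expect_equal(unname(counts["discarded_weak"]), 49)
  expect_equal(unname(counts["preselected"]), 60)
  expect_setequal(res$drug, drugs)

  # all inactive -> nothing preselected
  allna <- tibble::tibble(drug = c("a", "b"), sample = "s",
                          min_active_nM = NA_real_)
  expect_true(all(triage_panel(allna)$category == "discarded_inactive"))
  expect_error(triage_panel(dplyr::mutate(allna, min_active_nM = -1)),
               "negative")
})

test_that("triage equals the set-comprehension oracle on random tables", {
  withr::with_seed(42, {
    for (i in 1:15) {
      nd <- sample(3:12, 1); ns <- sample(1:4, 1)
      activity <- tidyr::crossing(drug = sprintf("d%02d", 1:nd),
                                  sample = sprintf("s%d", 1:ns)) |>
        dplyr::mutate(min_active_nM = ifelse(runif(dplyr::n()) < 0.3, NA,
                                             10^runif(dplyr::n(), 0, 4)))
      thr <- 10^runif(1, 1, 3.5)
      got <- triage_panel(activity, thr) |> dplyr::arrange(drug)
      want <- bf_triage(activity, thr) |> dplyr::arrange(drug)
      expect_equal(got$drug, want$drug)
      expect_equal(got$category, want$category)
    }
  })
})
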