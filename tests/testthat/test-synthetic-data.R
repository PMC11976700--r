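test_that("resolution outcomes follow the two-enantiomer first-order model", {
  # unselective limit: both ee vanish at any conversion
  obs <- simulate_resolution_outcome(1, 0.40)
  expect_equal(obs$ee_p, 0)
  expect_equal(obs$ee_s, 0)
  # perfect resolution below 50% conversion: ee_p = 1
  obs <- simulate_resolution_outcome(Inf, 0.30)
  expect_equal(obs$ee_p, 1.0, tolerance = 1e-6)
  # the WT-like case, against the closed-form E
  obs <- simulate_resolution_outcome(22.4, 0.465)
  expect_equal(obs$conversion, 0.465)
  expect_equal(obs$ee_p, 0.826, tolerance = 2e-3)
  expect_error(simulate_resolution_outcome(0.5, 0.3),
               class = "halocat_invalid_parameter")
})

test_that("resolution generator round-trips through the E-value closed form", {
  for (e in c(1.3, 2, 5, 22.4, 74, 200, 500)) {
    for (cv in c(0.05, 0.3, 0.465, 0.7, 0.95)) {
      obs <- simulate_resolution_outcome(e, cv)
      if (obs$conversion * (1 + obs$ee_p) >= 1) next  # infeasible printouts
      expect_equal(e_from_c_eep(obs$conversion, obs$ee_p)$e_value, e,
                   tolerance = 1e-6, info = sprintf("E=%g C=%g", e, cv))
    }
  }
})

test_that("progress curves integrate enzymatic plus background kinetics", {
  # flat zero when nothing reacts
  tk0 <- true_kinetics("hill", 1, 1, 1, 0)
  out <- simulate_progress_curve(tk0, 10, 0, c(30, 60, 120))
  expect_equal(out$catalyzed$product, rep(0, 3))
  # pure first-order background matches the closed-form integral
  tkb <- true_kinetics("hill", 0, 1, 1, 1e-3)
  out <- simulate_progress_curve(tkb, 10, 0, c(30, 360))
  expect_equal(out$background$product, 10 * (1 - exp(-1e-3 * c(30, 360))),
               tolerance = 1e-8)
  # saturating limit: initial rate = [E] * vmax within 1%
  tks <- true_kinetics("michaelis_menten", 5, 0.01)
  out <- simulate_progress_curve(tks, 100, 1e-3, c(1, 2))
  expect_equal(out$catalyzed$product[1] / 1, 1e-3 * 5, tolerance = 0.01)
  # curves are monotone and bounded by s0
  tk <- true_kinetics("hill", 10, 5, 2, 1e-4)
  out <- simulate_progress_curve(tk, 10, 1e-3, seq(30, 3600, by = 30))
  expect_true(all(diff(out$catalyzed$product) >= 0))
  expect_true(all(out$catalyzed$product <= 10 + 1e-9))
  expect_error(simulate_progress_curve(tk, -1, 0, 30),
               class = "halocat_invalid_parameter")
  expect_error(simulate_progress_curve(tk, 10, 1e-3, c(60, 30)),
               class = "halocat_invalid_parameter")
})

test_that("initial slope of the noiseless background-subtracted curve obeys the rate law", {
  tk <- true_kinetics("hill", 8.16, 18.8, 1.70, 5e-5)
  s0 <- 10; esite <- 2e-4
  out <- simulate_progress_curve(tk, s0, esite, c(1, 2))
  v0 <- (out$catalyzed$product[1] - out$background$product[1]) / 1
  expected <- esite * 8.16 * s0^1.7 / (18.8^1.7 + s0^1.7)
  expect_equal(v0, expected, tolerance = 0.01)
})

test_that("plate-read generation inverts the quantification chain exactly at zero noise", {
  for (seed in 1:5) {
    case <- random_roundtrip_case(seed)
    ts <- simulate_plate_timeseries(case$curve, case$scenario)
    back <- quantify_timeseries(ts, case$scenario)
    expect_lt(max(abs(back$product - case$curve$product)), 1e-9)
  }
  # and with the minor buffering terms switched on, on both sides
  case <- random_roundtrip_case(11)
  ts <- simulate_plate_timeseries(case$curve, case$scenario,
                                  include_minor_terms = TRUE)
  back <- quantify_timeseries(ts, case$scenario, include_minor_terms = TRUE)
  expect_lt(max(abs(back$product - case$curve$product)), 1e-9)
})

test_that("plate-read generation is seed-deterministic and flags pH excursions", {
  case <- random_roundtrip_case(3)
  a <- simulate_plate_timeseries(case$curve, case$scenario, noise_sd = 0.01,
                                 seed = 42)
  b <- simulate_plate_timeseries(case$curve, case$scenario, noise_sd = 0.01,
                                 seed = 42)
  expect_identical(a, b)
  # zero product keeps the ratio constant at its t = 0 value
  flat <- progress_curve(c(0, 60, 120), c(0, 0, 0), substrate0 = 10)
  ts <- simulate_plate_timeseries(flat, case$scenario)
  expect_equal(ts$a_report / ts$a_iso,
               rep(ts$a_report[1] / ts$a_iso[1], 3))
  # an excursion beyond the indicator's range names the offending timepoint
  big <- progress_curve(c(0, 60), c(0, 5), substrate0 = 10)
  scen <- assay_scenario(indicator_calibration(), buffer = buffer_spec(1),
                         substrate0 = 10)
  expect_error(simulate_plate_timeseries(big, scen), regexp = "t = 60",
               class = "halocat_range_error")
})

test_that("rate datasets apply multiplicative CV noise around the true law", {
  tk <- true_kinetics("hill", 60.2, 14.2, 2.32)
  d0 <- simulate_rate_dataset(tk, c(1, 5, 15, 50, 150), replicates = 1, cv = 0)
  expect_equal(d0$rate, 60.2 * d0$s^2.32 / (14.2^2.32 + d0$s^2.32))
  d1 <- simulate_rate_dataset(tk, c(1, 5, 15, 50, 150), replicates = 2,
                              cv = 0.02, seed = 9)
  d2 <- simulate_rate_dataset(tk, c(1, 5, 15, 50, 150), replicates = 2,
                              cv = 0.02, seed = 9)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 10)
})

test_that("simulated ensembles converge to their target correlations", {
  set.seed(1)
  coords <- matrix(rnorm(12 * 3), 12, 3) * 5
  # identity target: off-diagonal DCCM is sampling noise, < 0.1 at 5000 frames
  spec <- ensemble_spec(coords, diag(12), n_frames = 5000, seed = 2)
  cm <- dccm(simulate_ensemble(spec))
  off <- cm[upper.tri(cm)]
  expect_lt(max(abs(off)), 0.1)
  # +1 and -1 targets are exact by construction
  ct <- diag(4); ct[1, 2] <- ct[2, 1] <- 1; ct[3, 4] <- ct[4, 3] <- -1
  spec <- ensemble_spec(coords[1:4, ], ct, n_frames = 200, seed = 3)
  cm <- dccm(simulate_ensemble(spec))
  expect_equal(cm[1, 2], 1, tolerance = 1e-9)
  expect_equal(cm[3, 4], -1, tolerance = 1e-9)
  # seeded reproducibility
  e1 <- simulate_ensemble(spec); e2 <- simulate_ensemble(spec)
  expect_identical(e1$frames, e2$frames)
  # non-PSD targets are rejected
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_error(ensemble_spec(coords[1:3, ], bad),
               class = "halocat_invalid_parameter")
})

test_that("melt-curve generator produces the logistic it claims", {
  grid <- seq(10, 90, by = 0.5)
  mc <- simulate_melt_curve(50, 1.5, plateaus = c(2, 7), t_grid = grid)
  expect_equal(mc$fluorescence, logistic_melt(grid, 50, 1.5, 2, 7))
  expect_error(simulate_melt_curve(50, 0), class = "halocat_invalid_parameter")
  expect_error(simulate_melt_curve(50, 1.5, t_grid = seq(40, 60, by = 5)),
               class = "halocat_invalid_parameter")
  a <- simulate_melt_curve(50, 1.5, noise_sd = 0.01, seed = 5)
  b <- simulate_melt_curve(50, 1.5, noise_sd = 0.01, seed = 5)
  expect_identical(a, b)
})
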