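test_that("initial rates come from the early-window OLS slope", {
  pc <- progress_curve(c(30, 60, 180, 270, 360), c(0.1, 0.2, 0.6, 0.9, 1.2),
                       substrate0 = 100)
  r <- initial_rate(pc)
  expect_equal(r$v0, 1 / 300)
  expect_equal(r$stderr, 0, tolerance = 1e-12)
  expect_equal(r$n_points_used, 5L)
  # identical blank self-subtracts to zero
  r0 <- initial_rate(pc, blank = pc)
  expect_equal(r0$v0, 0)
  # all-zero curve
  z <- progress_curve(c(30, 60, 180), c(0, 0, 0), substrate0 = 10)
  rz <- initial_rate(z)
  expect_equal(rz$v0, 0)
  expect_equal(rz$stderr, 0)
})

test_that("the linear window respects the conversion ceiling with a 3-point floor", {
  # curvature past 10% conversion must be excluded
  tt <- c(30, 60, 90, 600, 1200)
  pp <- c(0.3, 0.6, 0.9, 4.5, 6.0)  # linear early, saturating late (s0 = 10)
  pc <- progress_curve(tt, pp, substrate0 = 10)
  r <- initial_rate(pc)
  expect_equal(r$n_points_used, 3L)
  expect_equal(r$v0, 0.01)
  # when even the first points exceed the ceiling, the 3 earliest are kept
  pc2 <- progress_curve(c(30, 60, 90, 120), c(3, 5, 6, 6.5), substrate0 = 10)
  r2 <- initial_rate(pc2)
  expect_equal(r2$n_points_used, 3L)
  expect_error(initial_rate(progress_curve(30, 0.1, substrate0 = 10)),
               class = "halocat_insufficient_data")
})

test_that("initial rate is invariant to a constant product offset", {
  pc <- progress_curve(c(30, 60, 180, 270), c(0.11, 0.19, 0.62, 0.88),
                       substrate0 = 100)
  shifted <- progress_curve(pc$time_s, pc$product + 0.5, substrate0 = 100)
  expect_equal(initial_rate(shifted)$v0, initial_rate(pc)$v0,
               tolerance = 1e-12)
})

test_that("specific activity does the U/mg unit arithmetic", {
  r <- structure(list(v0 = 1 / 300, stderr = 1e-4, n_points_used = 5,
                      window_end = 360), class = "rate_estimate")
  sa <- specific_activity(r, 0.02)
  expect_equal(sa$value, 10.0)
  # doubling the loading halves the value
  expect_equal(specific_activity(r, 0.04)$value, 5.0)
  r$v0 <- 0
  expect_equal(specific_activity(r, 0.02)$value, 0)
  expect_error(specific_activity(r, 0), class = "halocat_invalid_parameter")
})

test_that("per-site concentration converts loading and subunit mass", {
  # 0.0254 mg/mL of a 25.4 kDa subunit is 1 uM = 1e-3 mM of sites
  expect_equal(per_site_concentration(0.0254, 25400), 1e-3)
})

test_that("Michaelis-Menten fitting recovers noiseless truth exactly", {
  tk <- true_kinetics("michaelis_menten", 6.30, 0.98)
  d <- simulate_rate_dataset(tk, exp(seq(log(0.01), log(20), length.out = 12)),
                             replicates = 1, cv = 0)
  f <- fit_michaelis_menten(d)
  expect_equal(f$kcat, 6.30, tolerance = 1e-6)
  expect_equal(f$km, 0.98, tolerance = 1e-6)
  expect_equal(f$efficiency, f$kcat / f$km)
  # saturating limit: the generating law itself approaches kcat at S >> Km
  sat <- simulate_rate_dataset(tk, 1e3 * 0.98, replicates = 1, cv = 0)
  expect_equal(sat$rate, 6.30, tolerance = 0.01)
})

test_that("Hill fitting recovers noiseless truth and honors the midpoint identity", {
  tk <- true_kinetics("hill", 60.2, 14.2, 2.32)
  d <- simulate_rate_dataset(tk, exp(seq(log(1), log(150), length.out = 12)),
                             replicates = 1, cv = 0)
  f <- fit_hill(d)
  expect_equal(f$kobs_max, 60.2, tolerance = 1e-6)
  expect_equal(f$k50, 14.2, tolerance = 1e-6)
  expect_equal(f$n_h, 2.32, tolerance = 1e-6)
  # the fitted curve passes through kobs_max/2 at S = K50 whatever n_H is
  expect_equal(f$kobs_max * f$k50^f$n_h / (f$k50^f$n_h + f$k50^f$n_h),
               f$kobs_max / 2)
})

test_that("Hill with n_H fixed at 1 reproduces the Michaelis-Menten fit", {
  tk <- true_kinetics("michaelis_menten", 2.0, 3.0)
  d <- simulate_rate_dataset(tk, c(0.3, 1, 3, 10, 30, 100), replicates = 2,
                             cv = 0.03, seed = 4)
  mm <- fit_michaelis_menten(d)
  h1 <- fit_hill(d, fix_nh = 1)
  expect_equal(h1$kobs_max, mm$kcat, tolerance = 1e-6)
  expect_equal(h1$k50, mm$km, tolerance = 1e-6)
})

test_that("noisy recovery stays within 10% at 2% CV", {
  tk <- true_kinetics("michaelis_menten", 6.30, 0.98)
  d <- simulate_rate_dataset(tk, exp(seq(log(0.01), log(20), length.out = 12)),
                             replicates = 1, cv = 0.05, seed = 21)
  f <- fit_michaelis_menten(d)
  expect_lt(abs(f$kcat - 6.30) / 6.30, 0.10)
  expect_lt(abs(f$km - 0.98) / 0.98, 0.10)
})

test_that("replicated parameter recovery is accurate across cooperativity levels", {
  # median relative errors over seeded replicates at 2% CV:
  # K50 and kobs_max below 5%, n_H below 10%
  truths <- list(c(25.4, 40.3, 1.14), c(60.2, 14.2, 2.32), c(0.78, 49.5, 4.58))
  conc <- exp(seq(log(1), log(150), length.out = 12))
  for (tr in truths) {
    tk <- true_kinetics("hill", tr[1], tr[2], tr[3])
    errs <- t(vapply(1:70, function(seed) {
      d <- simulate_rate_dataset(tk, conc, replicates = 2, cv = 0.02,
                                 seed = seed)
      f <- fit_hill(d)
      c(abs(f$kobs_max - tr[1]) / tr[1], abs(f$k50 - tr[2]) / tr[2],
        abs(f$n_h - tr[3]) / tr[3])
    }, numeric(3)))
    med <- apply(errs, 2, stats::median)
    expect_lt(med[1], 0.05)
    expect_lt(med[2], 0.05)
    expect_lt(med[3], 0.10)
  }
})

test_that("inadequate designs and weighting inputs are rejected or used", {
  tk <- true_kinetics("hill", 10, 5, 2)
  d4 <- simulate_rate_dataset(tk, c(1, 2, 5, 10), replicates = 1, cv = 0)
  expect_error(fit_hill(d4), class = "halocat_insufficient_data")
  # inverse-variance weights are accepted and leave a noiseless fit exact
  d <- simulate_rate_dataset(tk, c(0.5, 2, 5, 10, 30, 100), replicates = 1,
                             cv = 0)
  dw <- kinetic_dataset(d$s, d$rate, sd = rep(0.05, nrow(d)))
  f <- fit_hill(dw)
  expect_equal(f$k50, 5, tolerance = 1e-6)
})
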