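# Forward model, inversion efficiency, nulling time.

test_that("inversion efficiency is zero at zero power, saturating, monotone", {
  expect_equal(inversion_efficiency(0), 0)
  expect_equal(inversion_efficiency(1e6), 1)
  expect_gt(inversion_efficiency(3), inversion_efficiency(1))
  expect_gte(inversion_efficiency(3), 0.95)
  p <- seq(0, 6, by = 0.5)
  expect_true(all(diff(inversion_efficiency(p)) > 0))
  expect_error(inversion_efficiency(-0.1), "power")
})

test_that("nulling time matches a bisection oracle and the classic limits", {
  # classic single-shot null point
  expect_equal(nulling_time(2100, Inf, 1), 2100 * log(2), tolerance = 1e-12)
  # algebraic case TR = T1, e = 1
  expect_equal(nulling_time(2100, 2100, 1), 2100 * log(2 / (1 + exp(-1))),
               tolerance = 1e-12)
  # bisection oracle on the steady-state residual
  oracle <- function(t1, tr, e) {
    f <- function(ti) 1 - (1 + e) * exp(-ti / t1) + e * exp(-tr / t1)
    uniroot(f, c(1e-6, tr - 1e-6), tol = 1e-8)$root
  }
  for (case in list(c(2100, 6000, 1), c(2100, 6000, 0.95),
                    c(1800, 5000, 0.8), c(2300, 8000, 0.99))) {
    expect_lt(abs(nulling_time(case[1], case[2], case[3]) -
                    oracle(case[1], case[2], case[3])), 0.1)
  }
  expect_error(nulling_time(-1, 6000, 1), "t1_blood_ms")
  expect_error(nulling_time(2100, 6000, 0), "efficiency")
  expect_error(nulling_time(2100, 6000, 1.5), "efficiency")
})

test_that("acquisition parameter invariants are enforced", {
  p <- acquisition_params()
  expect_equal(p$tr_pair_ms, 2 * p$tr_image_ms)
  expect_equal(run_duration_min(p), 15.4)
  expect_error(acquisition_params(tr_pair_ms = 5000), "tr_pair_ms")
  expect_error(acquisition_params(n_timepoints = 307), "even")
  expect_error(acquisition_params(ti1_ms = 7000), "ti1_ms")
})

test_that("simulation yields alternating tags and correct volume count", {
  run <- noisefree_run()
  ser <- run$series
  expect_equal(dim(ser$data)[4], 308)
  expect_identical(ser$contrast_tag, rep(c("nulled", "notnulled"), 154))
  expect_equal(diff(ser$timestamp_ms), rep(3000, 307))
})

test_that("zero response, noise and drift give constant series", {
  tr <- ground_truth(bold_scale = 0, cbv_scale = 0, noise_sd = 0,
                     drift_coeffs = c(0, 0), inflow_amplitude = 0)
  ph <- small_phantom(truth = tr)
  des <- make_task_design(2)
  ser <- simulate_interleaved(ph, des, acquisition_params(n_timepoints = 12),
                              noise_sd = 0, drift = FALSE)
  m <- matrix(ser$data, 32^3, 12)
  expect_equal(apply(m, 1, function(x) max(x) - min(x)), rep(0, 32^3))
})

test_that("plateau nulled/notnulled ratio follows the closed-form model", {
  # one bin carries CBV amplitude a; during the sustained plateau the
  # pairwise ratio equals 1 - a * h(t) with h the convolved regressor
  a <- 0.02
  tr <- ground_truth(bold_scale = 0, cbv_scale = 0, noise_sd = 0,
                     drift_coeffs = c(0, 0), inflow_amplitude = 0)
  # pick a depth bin that is actually populated in the coarse small phantom
  probe <- small_phantom()
  bin <- probe$vox_bin[probe$vox_subfield == "CA1" & probe$vox_bin >= 11][1]
  tr$cbv_profile$CA1 <- rep(0, 30)
  tr$cbv_profile$CA1[bin] <- a
  ph <- small_phantom(truth = tr)
  des <- make_task_design(2)
  par <- acquisition_params(n_timepoints = 40)
  ser <- simulate_interleaved(ph, des, par, noise_sd = 0, drift = FALSE)
  vox <- ph$signal_vox[ph$vox_subfield == "CA1" & ph$vox_bin == bin][1]
  m <- matrix(ser$data, 32^3, 40)
  ratio <- m[vox, seq(1, 39, 2)] / m[vox, seq(2, 40, 2)]
  pair_s <- ser$timestamp_ms[seq(1, 39, 2)] / 1000
  h <- task_regressor(des$events, pair_s, "memory")
  expect_equal(ratio, 1 - a * h, tolerance = 1e-12)
})

test_that("simulation is deterministic for a fixed seed", {
  ph <- small_phantom()
  des <- make_task_design(2)
  par <- acquisition_params(n_timepoints = 8)
  s1 <- simulate_interleaved(ph, des, par, seed = 11)
  s2 <- simulate_interleaved(ph, des, par, seed = 11)
  s3 <- simulate_interleaved(ph, des, par, seed = 12)
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data, s3$data))
})

test_that("inflow excess on nulled volumes scales with 1 - efficiency", {
  tr <- ground_truth(bold_scale = 0, cbv_scale = 0, noise_sd = 0,
                     drift_coeffs = c(0, 0), inflow_amplitude = 25)
  ph <- small_phantom(truth = tr)
  des <- make_task_design(1)
  vessel <- phantom_mask(ph, "vessel")
  for (pw in c(0, 2)) {
    par <- acquisition_params(n_timepoints = 4, rf_power_scale = pw)
    ser <- simulate_interleaved(ph, des, par, noise_sd = 0, drift = FALSE)
    nulled <- ser$data[, , , 1][vessel]
    notnulled <- ser$data[, , , 2][vessel]
    expect_equal(mean(nulled - notnulled), 25 * (1 - inversion_efficiency(pw)),
                 tolerance = 1e-9)
  }
})
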