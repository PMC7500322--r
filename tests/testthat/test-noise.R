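test_that("smooth Gaussian noise is reproducible, unit-variance and smooth", {
  n1 <- smooth_gaussian_noise(500, 120, 0.05, seed = 3)
  n2 <- smooth_gaussian_noise(500, 120, 0.05, seed = 3)
  expect_identical(n1, n2)

  big <- smooth_gaussian_noise(1e5, 120, 0.05, seed = 4)
  expect_gt(var(big), 0.9)
  expect_lt(var(big), 1.1)
  expect_lt(abs(mean(big)), 0.05)

  # Gaussian autocorrelation: rho(fwhm / 2) = 0.5
  lag <- round(0.05 * 120 / 2)
  rho <- cor(big[-(1:lag)], big[seq_len(length(big) - lag)])
  expect_gt(rho, 0.4)
  expect_lt(rho, 0.6)
})

test_that("noise smoother than the sampling grid is rejected", {
  expect_error(smooth_gaussian_noise(100, 120, 0.001), "fwhm")
})

test_that("endpoint weighting is zero at the ends, symmetric, and ~1 inside", {
  n <- 49
  w <- endpoint_weighting(n, 120, taper_tau = 0.4 / 20)
  expect_identical(w[1], 0)
  expect_identical(w[n], 0)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(w, rev(w), tolerance = 1e-12)
  expect_gte(w[(n + 1) / 2], 0.99)
  expect_error(endpoint_weighting(n, 120, taper_tau = 0.3), "taper_tau")
})

test_that("synthesized trajectories preserve endpoints exactly for any draw", {
  mj <- hack_minjerk()
  n <- length(mj$theta)
  for (s in 1:100) {
    spec <- smooth_noise_spec(sd = runif(1, 0.1, 4), amp_scale = 2.3,
                              seed = s)
    synth <- synthesize_trajectory(mj, spec)
    expect_identical(synth$theta[1], mj$theta[1])
    expect_identical(synth$theta[n], mj$theta[n])
  }
})

test_that("zero noise amplitude returns the minimum-jerk input bit-identically", {
  mj <- hack_minjerk()
  spec <- smooth_noise_spec(sd = 0, amp_scale = 2.3, seed = 9)
  expect_identical(synthesize_trajectory(mj, spec), mj)
})

test_that("expected jerk increases with noise amplitude over the SD grid", {
  mj <- hack_minjerk()
  grid <- c(0, seq(0.5, 4, by = 0.5))
  n_draws <- 200
  means <- vapply(grid, function(sdv) {
    if (sdv == 0) return(jerk_pipeline(mj))
    jerks <- vapply(seq_len(n_draws), function(s) {
      spec <- smooth_noise_spec(sd = sdv, amp_scale = 2.3,
                                seed = 7000 + s)
      jerk_pipeline(synthesize_trajectory(mj, spec))
    }, numeric(1))
    mean(jerks)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("calibration hits the target jerk and behaves in its limits", {
  mj <- hack_minjerk()
  cal <- calibration_fixture()
  expect_equal(cal$achieved, 0.5e5, tolerance = 0.005)
  expect_gt(cal$amp_scale, 0)

  # fresh draws at the calibrated amplitude agree with the target within
  # Monte-Carlo error
  seeds <- 30001:30400
  jerks <- vapply(seeds, function(s) {
    spec <- smooth_noise_spec(sd = 0.5, fwhm = cal$fwhm,
                              amp_scale = cal$amp_scale,
                              taper_tau = cal$taper_tau, seed = s)
    jerk_pipeline(synthesize_trajectory(mj, spec))
  }, numeric(1))
  se <- sd(jerks) * sqrt(1 / length(jerks) + 1 / cal$n_draws)
  expect_lt(abs(mean(jerks) - 0.5e5), 3 * se)

  # limit case: target equal to the baseline gives zero amplitude
  baseline <- jerk_pipeline(mj)
  cal0 <- calibrate_noise_units(mj, baseline, seed = 1)
  expect_identical(cal0$amp_scale, 0)

  # unattainable target errors
  expect_error(calibrate_noise_units(mj, baseline / 2, seed = 1),
               "unattainable")
})

test_that("doubling the amplitude never decreases the mean jerk", {
  mj <- hack_minjerk()
  mean_jerk <- function(amp) {
    mean(vapply(1:60, function(s) {
      spec <- smooth_noise_spec(sd = 0.5, amp_scale = amp, seed = 400 + s)
      jerk_pipeline(synthesize_trajectory(mj, spec))
    }, numeric(1)))
  }
  expect_gt(mean_jerk(4), mean_jerk(2))
  expect_gt(mean_jerk(2), mean_jerk(1))
})

test_that("the default grid yields nine conditions anchored at the minimum-jerk trajectory", {
  cs <- calibrated_set()
  expect_equal(nrow(cs$conditions), 9L)
  expect_identical(cs$conditions$sd, c(0, seq(0.5, 4, by = 0.5)))
  mj <- hack_minjerk()
  expect_identical(cs$trajectories[[1]]$theta, mj$theta)
  expect_equal(cs$conditions$realized_jerk[1], jerk_pipeline(mj))
})

test_that("condition sets are bit-reproducible under a fixed seed", {
  cal <- calibration_fixture()
  cs1 <- generate_condition_set(seed = 202, calibration = cal)
  cs2 <- generate_condition_set(seed = 202, calibration = cal)
  expect_identical(cs1$conditions, cs2$conditions)
  expect_identical(cs1$trajectories, cs2$trajectories)
})

test_that("condition sets survive a disk round trip and jerks recompute", {
  cs <- calibrated_set()
  dir <- tempfile("condset")
  on.exit(unlink(dir, recursive = TRUE))
  write_condition_set(cs, dir)
  back <- read_condition_set(dir)
  expect_equal(back$conditions$realized_jerk, cs$conditions$realized_jerk)
  for (i in seq_along(back$trajectories)) {
    recomputed <- jerk_pipeline(back$trajectories[[i]])
    expect_equal(recomputed, back$conditions$realized_jerk[i],
                 tolerance = 1e-9)
  }
})

test_that("animation cycles pad with holds without touching the motion jerk", {
  mj <- hack_minjerk()
  cycle <- assemble_animation_cycle(mj, 0.8, 0.8)
  expect_equal(cycle$t[length(cycle$t)] - cycle$t[1], 2.0)
  expect_true(all(cycle$theta[cycle$t < 0.8] == mj$theta[1]))
  expect_true(all(cycle$theta[cycle$t > 1.2] == mj$theta[length(mj$theta)]))
  expect_identical(assemble_animation_cycle(mj, 0, 0), mj)

  # jerk over the detected motion segment is unchanged by padding
  spec <- smooth_noise_spec(sd = 1.5, amp_scale = 2.3, seed = 12)
  synth <- synthesize_trajectory(mj, spec)
  j_short <- jerk_pipeline(synth, pre_hold = 0.4, post_hold = 0.4,
                           cutoff = NULL, segment = "detect")
  j_long <- jerk_pipeline(synth, pre_hold = 1.2, post_hold = 0.8,
                          cutoff = NULL, segment = "detect")
  expect_equal(j_short, j_long, tolerance = 1e-9)
})
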