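test_that("minimum-jerk trajectory honours its endpoint and symmetry contracts", {
  tr <- hack_minjerk()
  expect_identical(tr$theta[1], hack_xi)
  expect_identical(tr$theta[length(tr$theta)], hack_xf)
  # midpoint is the average of the endpoints (quintic symmetry)
  mid <- tr$theta[tr$t == hack_d / 2]
  expect_equal(mid, (hack_xi + hack_xf) / 2)
  # monotone between endpoints
  expect_true(all(diff(tr$theta) <= 0))
  # endpoint velocity and acceleration vanish (second-order one-sided
  # stencils; bounds are small fractions of the peak values 1.875|d|/d and
  # 5.77|d|/d^2)
  h <- 1 / tr$rate
  th <- tr$theta
  v0 <- (-1.5 * th[1] + 2 * th[2] - 0.5 * th[3]) / h
  a0 <- (2 * th[1] - 5 * th[2] + 4 * th[3] - th[4]) / h^2
  expect_lt(abs(v0), 0.01 * 1.875 * abs(hack_xf - hack_xi) / hack_d)
  expect_lt(abs(a0), 0.05 * 5.77 * abs(hack_xf - hack_xi) / hack_d^2)
})

test_that("zero-displacement spec yields a constant trajectory", {
  tr <- minimum_jerk_trajectory(100, 100, 0.4, 120)
  expect_true(all(tr$theta == 100))
  expect_equal(average_absolute_jerk(tr), 0)
})

test_that("invalid minimum-jerk parameters are rejected", {
  expect_error(minimum_jerk_trajectory(1, 2, -0.4, 120), "positive")
  expect_error(minimum_jerk_trajectory(1, 2, 0.4, -120), "positive")
  expect_error(minimum_jerk_trajectory(1, 2, 10, 0.1), "rate")
})

test_that("average absolute jerk converges to the closed form on dense grids", {
  # closed form 40|delta|/(sqrt(3) d^3), cross-checked by quadrature
  delta <- hack_xf - hack_xi
  cf <- minimum_jerk_avg_abs_jerk(hack_xi, hack_xf, hack_d)
  expect_equal(cf, quadrature_avg_jerk(abs(delta), hack_d),
               tolerance = 1e-4)
  tr <- minimum_jerk_trajectory(hack_xi, hack_xf, hack_d, 1e4)
  expect_lt(abs(average_absolute_jerk(tr) - cf) / cf, 0.01)
})

test_that("average absolute jerk scales linearly in displacement and as d^-3", {
  base <- average_absolute_jerk(minimum_jerk_trajectory(0, 10, 0.5, 1000))
  for (mult in c(2, 5)) {
    sc <- average_absolute_jerk(minimum_jerk_trajectory(0, 10 * mult, 0.5,
                                                        1000))
    expect_equal(sc / base, mult, tolerance = 1e-9)
  }
  for (d2 in c(0.25, 1)) {
    sc <- average_absolute_jerk(minimum_jerk_trajectory(0, 10, d2, 1000))
    expect_equal(sc / base, (0.5 / d2)^3, tolerance = 1e-2)
  }
})

test_that("jerk metric rejects segments outside the trajectory", {
  tr <- hack_minjerk()
  expect_error(average_absolute_jerk(tr, movement_segment(-0.5, 0.2)),
               "outside")
  expect_error(average_absolute_jerk(tr, movement_segment(0.1, 9)),
               "outside")
  expect_error(movement_segment(0.3, 0.1), "t0 < t_end")
})

test_that("zero-phase filter preserves constants and reduces variance", {
  const <- joint_trajectory(seq(0, 1, by = 1 / 120), rep(50, 121))
  out <- lowpass_zero_phase(const, 10, 5)
  expect_equal(out$theta, const$theta, tolerance = 1e-8)

  set.seed(42)
  noisy <- joint_trajectory(seq(0, 5, by = 1 / 120),
                            rnorm(601))
  filt <- lowpass_zero_phase(noisy, 10, 5)
  expect_length(filt$theta, length(noisy$theta))
  expect_lt(var(filt$theta), var(noisy$theta))
})

test_that("a 1 Hz sinusoid passes a 10 Hz cutoff with <1% attenuation", {
  t <- seq(0, 10, by = 1 / 120)
  tr <- joint_trajectory(t, sin(2 * pi * t))
  filt <- lowpass_zero_phase(tr, 10, 5)
  interior <- t > 2 & t < 8  # avoid filtfilt edge transients
  amp <- max(abs(filt$theta[interior]))
  expect_gt(amp, 0.99)
  expect_lt(amp, 1.01)
})

test_that("cutoff at or above Nyquist is a parameter error", {
  tr <- hack_minjerk()
  expect_error(lowpass_zero_phase(tr, 60, 5), "Nyquist")
  expect_error(lowpass_zero_phase(tr, 75, 5), "Nyquist")
})

test_that("filtering never increases the jerk statistic when repeated", {
  set.seed(7)
  spec <- smooth_noise_spec(sd = 2, amp_scale = 3, seed = 11)
  tr <- synthesize_trajectory(hack_minjerk(), spec)
  once <- lowpass_zero_phase(tr, 10, 5)
  twice <- lowpass_zero_phase(once, 10, 5)
  expect_lte(average_absolute_jerk(twice),
             average_absolute_jerk(once) * (1 + 1e-9))
})

test_that("marker joint angles match the vector-algebra oracle", {
  # collinear with the joint between the others: straight finger, 180 deg
  n <- 5
  t <- seq(0, 1, length.out = n)
  straight <- marker_frames(t, data.frame(
    PIP_x = rep(2, n), PIP_y = 0, PIP_z = 0,
    MPjoint_x = rep(1, n), MPjoint_y = 0, MPjoint_z = 0,
    MPbone_x = rep(0, n), MPbone_y = 0, MPbone_z = 0))
  expect_equal(joint_angle_from_markers(straight)$theta, rep(180, n))

  right <- marker_frames(t, data.frame(
    PIP_x = rep(1, n), PIP_y = 1, PIP_z = 0,
    MPjoint_x = rep(1, n), MPjoint_y = 0, MPjoint_z = 0,
    MPbone_x = rep(0, n), MPbone_y = 0, MPbone_z = 0))
  expect_equal(joint_angle_from_markers(right)$theta, rep(90, n))

  set.seed(5)
  for (rep_i in 1:20) {
    pts <- matrix(rnorm(9), 3, 3)
    frames <- marker_frames(t, data.frame(
      PIP_x = rep(pts[1, 1], n), PIP_y = pts[1, 2], PIP_z = pts[1, 3],
      MPjoint_x = pts[2, 1], MPjoint_y = pts[2, 2], MPjoint_z = pts[2, 3],
      MPbone_x = pts[3, 1], MPbone_y = pts[3, 2], MPbone_z = pts[3, 3]))
    got <- joint_angle_from_markers(frames)$theta[1]
    expect_equal(got, angle_oracle(pts[1, ], pts[2, ], pts[3, ]),
                 tolerance = 1e-9)
    expect_gte(got, 0)
    expect_lte(got, 180)
  }
})

test_that("marker angles are invariant to rotation, translation and scaling", {
  set.seed(6)
  t <- seq(0, 1, length.out = 4)
  pts <- matrix(rnorm(9), 3, 3)
  as_frames <- function(m) {
    marker_frames(t, data.frame(
      PIP_x = rep(m[1, 1], 4), PIP_y = m[1, 2], PIP_z = m[1, 3],
      MPjoint_x = m[2, 1], MPjoint_y = m[2, 2], MPjoint_z = m[2, 3],
      MPbone_x = m[3, 1], MPbone_y = m[3, 2], MPbone_z = m[3, 3]))
  }
  base <- joint_angle_from_markers(as_frames(pts))$theta[1]
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  transformed <- 2.5 * pts %*% R + matrix(c(10, -3, 7), 3, 3, byrow = TRUE)
  expect_equal(joint_angle_from_markers(as_frames(transformed))$theta[1],
               base, tolerance = 1e-9)
})

test_that("coincident markers raise a degenerate-geometry error naming the frame", {
  t <- seq(0, 1, length.out = 4)
  frames <- marker_frames(t, data.frame(
    PIP_x = c(1, 1, 1, 1), PIP_y = 0, PIP_z = 0,
    MPjoint_x = c(0, 0, 1, 0), MPjoint_y = 0, MPjoint_z = 0,
    MPbone_x = -1, MPbone_y = 0, MPbone_z = 0))
  expect_error(joint_angle_from_markers(frames), "frame 3")
})

test_that("movement bounds from the velocity threshold match the quintic profile", {
  tr <- hack_minjerk()
  seg <- detect_movement_bounds(tr, 0.05)
  # analytic crossing of 5% peak velocity: 30 s^2 (1-s)^2 = 0.05 * 1.875
  expect_lt(seg$t0, hack_d / 2)
  expect_gt(seg$t_end, hack_d / 2)
  dur <- seg$t_end - seg$t0
  expect_gte(dur, 0.7 * hack_d)
  expect_lte(dur, hack_d)
})

test_that("constant trajectories yield a no-movement error", {
  const <- joint_trajectory(seq(0, 1, by = 1 / 120), rep(120, 121))
  expect_error(detect_movement_bounds(const), "no movement")
})

test_that("detected bounds are independent of static hold lengths", {
  tr <- hack_minjerk()
  pad1 <- assemble_animation_cycle(tr, 0.5, 0.5)
  pad2 <- assemble_animation_cycle(tr, 0.9, 0.3)
  s1 <- detect_movement_bounds(pad1)
  s2 <- detect_movement_bounds(pad2)
  expect_equal(s1$t0 - 0.5, s2$t0 - 0.9, tolerance = 1e-9)
  expect_equal(s1$t_end - s1$t0, s2$t_end - s2$t0, tolerance = 1e-9)
})

test_that("trajectory CSV round-trips exactly", {
  tr <- hack_minjerk()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$theta, tr$theta)
  expect_equal(back$rate, tr$rate, tolerance = 1e-9)
})
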