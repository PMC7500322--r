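# Jerk-controlled stimulus synthesis: endpoint-constrained, temporally
# smooth Gaussian noise added to the minimum-jerk trajectory, amplitude
# calibration in "SD" units, and assembly of the nine-condition set.

#' Smooth-noise specification
#'
#' Parameters of the endpoint-constrained smooth Gaussian noise added to a
#' minimum-jerk trajectory.  `sd` is the dimensionless noise amplitude of
#' the stimulus grid; physical degrees enter through `amp_scale`, the
#' calibration constant mapping one SD unit to degrees.
#'
#' @param sd Noise amplitude in SD grid units; `sd = 0` means no noise.
#' @param fwhm Temporal smoothness: full width at half maximum of the
#'   Gaussian autocorrelation of the noise, seconds.
#' @param amp_scale Degrees per SD unit (see [calibrate_noise_units()]).
#' @param taper_tau Endpoint-taper time constant, seconds.
#' @param seed RNG seed making the realization reproducible.
#' @return An object of class `smooth_noise_spec`.
#' @export
smooth_noise_spec <- function(sd, fwhm = 0.05, amp_scale = 1,
                              taper_tau = 0.02, seed = 1L) {
  if (sd < 0) stopf("sd must be non-negative")
  if (fwhm <= 0) stopf("fwhm must be positive")
  if (amp_scale <= 0) stopf("amp_scale must be positive")
  if (taper_tau <= 0) stopf("taper_tau must be positive")
  structure(list(sd = sd, fwhm = fwhm, amp_scale = amp_scale,
                 taper_tau = taper_tau, seed = as.integer(seed)),
            class = "smooth_noise_spec")
}

#' Temporally smooth Gaussian noise
#'
#' Stationary zero-mean Gaussian series with (in expectation) unit variance
#' and Gaussian autocorrelation of the stated FWHM, realized by convolving
#' white Gaussian noise with a Gaussian kernel and renormalizing the
#' variance.  The autocorrelation at lag `fwhm/2` is 0.5 by construction.
#'
#' @param n_samples Number of samples.
#' @param rate Sampling rate, Hz.
#' @param fwhm FWHM of the autocorrelation function, seconds; `fwhm * rate`
#'   must be at least 2 samples.
#' @param seed RNG seed.
#' @return Numeric vector of length `n_samples`.
#' @export
smooth_gaussian_noise <- function(n_samples, rate, fwhm, seed = NULL) {
  if (n_samples < 1) stopf("n_samples must be positive")
  if (fwhm * rate < 2) {
    stopf("fwhm (%.4g s) too small for rate %g Hz: fwhm * rate must be >= 2",
          fwhm, rate)
  }
  # kernel sd such that the smoothed field's Gaussian autocorrelation
  # (kernel self-convolution) has the requested FWHM
  sigma <- fwhm * rate / (2 * sqrt(2 * log(2))) / sqrt(2)
  half <- ceiling(4 * sigma)
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  white <- with_seed(seed, stats::rnorm(n_samples + 2L * half))
  sm <- stats::convolve(white, rev(k), type = "open")
  sm <- sm[(2L * half + 1L):(2L * half + n_samples)]
  sm / sqrt(sum(k^2))
}

#' Endpoint taper weights
#'
#' Weighting trajectory `w(t)` multiplying the noise so that synthesized
#' movements start and end exactly on the minimum-jerk endpoints:
#' \eqn{w(t) \propto (1 - e^{-t/\tau})(1 - e^{-(d - t)/\tau})}, rescaled to
#' a maximum of 1.  Exactly zero at both endpoints, symmetric about the
#' midpoint, and ~1 in the interior for small `taper_tau`.
#'
#' @param n_samples Number of samples covering the closed interval `[0, d]`.
#' @param rate Sampling rate, Hz (so `d = (n_samples - 1) / rate`).
#' @param taper_tau Taper time constant in seconds; must be below `d / 2`.
#' @return Numeric weight vector in `[0, 1]`.
#' @export
endpoint_weighting <- function(n_samples, rate, taper_tau) {
  if (n_samples < 3) stopf("need at least 3 samples")
  d <- (n_samples - 1) / rate
  if (taper_tau >= d / 2) {
    stopf("taper_tau (%.4g s) must be below half the duration (%.4g s)",
          taper_tau, d / 2)
  }
  t <- seq.int(0L, n_samples - 1L) / rate
  w <- (1 - exp(-t / taper_tau)) * (1 - exp(-(d - t) / taper_tau))
  w[1L] <- 0
  w[n_samples] <- 0
  w / max(w)
}

#' Add endpoint-constrained smooth noise to a trajectory
#'
#' Implements the stimulus construction
#' \eqn{x(t) = x_{\mathrm{minjerk}}(t) + \mathrm{SD}\cdot a \cdot n(t) w(t)}
#' where `n(t)` is unit-variance smooth Gaussian noise, `w(t)` the endpoint
#' taper and `a` the degree calibration `amp_scale`.  With `sd = 0` the
#' input is returned bit-identically; endpoints are preserved exactly for
#' every amplitude and seed.
#'
#' @param minjerk A [joint_trajectory], typically from
#'   [minimum_jerk_trajectory()].
#' @param noise_spec A [smooth_noise_spec].
#' @return A [joint_trajectory] on the same grid.
#' @export
synthesize_trajectory <- function(minjerk, noise_spec) {
  stopifnot(inherits(minjerk, "joint_trajectory"),
            inherits(noise_spec, "smooth_noise_spec"))
  if (noise_spec$sd == 0) return(minjerk)
  n <- length(minjerk$theta)
  noise <- smooth_gaussian_noise(n, minjerk$rate, noise_spec$fwhm,
                                 noise_spec$seed)
  w <- endpoint_weighting(n, minjerk$rate, noise_spec$taper_tau)
  theta <- minjerk$theta + noise_spec$amp_scale * noise_spec$sd * noise * w
  joint_trajectory(minjerk$t, theta, minjerk$rate)
}

#' Prepend and append static holds to a movement
#'
#' Builds the full animation cycle shown to observers: a static hold at the
#' initial posture, the movement, then a static hold at the final posture
#' (defaults 0.8 s + movement + 0.8 s, a 2.0 s cycle for a 0.4 s movement).
#'
#' @param motion A [joint_trajectory].
#' @param pre_hold,post_hold Hold durations in seconds (non-negative).
#' @return A [joint_trajectory] of total duration
#'   `pre_hold + duration + post_hold`.
#' @export
assemble_animation_cycle <- function(motion, pre_hold = 0.8, post_hold = 0.8) {
  stopifnot(inherits(motion, "joint_trajectory"))
  if (pre_hold < 0 || post_hold < 0) stopf("holds must be non-negative")
  rate <- motion$rate
  n_pre <- as.integer(round(pre_hold * rate))
  n_post <- as.integer(round(post_hold * rate))
  if (abs(n_pre - pre_hold * rate) > 1e-9 ||
      abs(n_post - post_hold * rate) > 1e-9) {
    stopf("hold durations must be whole numbers of sampling intervals")
  }
  if (n_pre == 0L && n_post == 0L) return(motion)
  theta <- c(rep(motion$theta[1L], n_pre), motion$theta,
             rep(motion$theta[length(motion$theta)], n_post))
  n <- length(theta)
  joint_trajectory(seq.int(0L, n - 1L) / rate, theta, rate)
}

# Mean realized jerk over noise draws at a given amplitude, using common
# random numbers (a fixed matrix of tapered noise realizations).
mean_jerk_at_amp <- function(minjerk, amp, noisew, pipeline_args) {
  jerks <- apply(noisew, 2L, function(nz) {
    traj <- joint_trajectory(minjerk$t, minjerk$theta + amp * nz,
                             minjerk$rate)
    do.call(jerk_pipeline, c(list(traj), pipeline_args))
  })
  mean(jerks)
}

#' Calibrate noise amplitude units against a target jerk
#'
#' Finds the calibration constant `amp_scale` (degrees per SD unit) such
#' that the Monte-Carlo mean average absolute jerk of synthesized
#' trajectories at `sd = 0.5` matches `target_jerk_at_half` — the jerk
#' level of recorded human grasping, which anchors the SD grid
#' (default target 0.5e5 deg/s^3).  The jerk of each draw is measured with
#' the same chain ([jerk_pipeline()]) used for the condition set.
#'
#' @param minjerk The reference [joint_trajectory].
#' @param target_jerk_at_half Target mean jerk at `sd = 0.5`, deg/s^3; must
#'   be at least the baseline jerk of `minjerk` itself.
#' @param fwhm,taper_tau Noise smoothness and taper settings (s).
#' @param n_draws Monte-Carlo draws used for the mean; default 200.
#' @param seed RNG seed for the draws.
#' @param pipeline_args List of arguments passed on to [jerk_pipeline()].
#' @param tol Relative tolerance on the achieved mean jerk; default 0.5%.
#' @return List with elements `amp_scale`, `fwhm`, `taper_tau`, `target`,
#'   `achieved`, `baseline`, `n_draws`, `seed` (class
#'   `noise_calibration`).
#' @export
calibrate_noise_units <- function(minjerk, target_jerk_at_half = 0.5e5,
                                  fwhm = 0.05, taper_tau = NULL,
                                  n_draws = 200, seed = 1L,
                                  pipeline_args = list(), tol = 0.005) {
  stopifnot(inherits(minjerk, "joint_trajectory"))
  n <- length(minjerk$theta)
  d <- minjerk$t[n] - minjerk$t[1]
  if (is.null(taper_tau)) taper_tau <- d / 20
  baseline <- do.call(jerk_pipeline, c(list(minjerk), pipeline_args))
  if (target_jerk_at_half < baseline * (1 - 1e-9)) {
    stopf(paste0("calibration target (%.4g) below the minimum-jerk baseline ",
                 "(%.4g): unattainable"), target_jerk_at_half, baseline)
  }
  out <- list(fwhm = fwhm, taper_tau = taper_tau,
              target = target_jerk_at_half, baseline = baseline,
              n_draws = n_draws, seed = as.integer(seed))
  if (abs(target_jerk_at_half - baseline) <= 1e-9 * baseline) {
    out$amp_scale <- 0
    out$achieved <- baseline
    class(out) <- "noise_calibration"
    return(out)
  }
  w <- endpoint_weighting(n, minjerk$rate, taper_tau)
  seeds <- derive_seeds(seed, n_draws)
  noisew <- vapply(seeds, function(s) {
    smooth_gaussian_noise(n, minjerk$rate, fwhm, s) * w
  }, numeric(n))
  # mean jerk is monotone in the amplitude: bracket then root-find;
  # amplitude here is amp_scale * 0.5 (the sd = 0.5 condition)
  g <- function(a) mean_jerk_at_amp(minjerk, a, noisew, pipeline_args) -
    target_jerk_at_half
  hi <- 1
  while (g(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e6) stopf("calibration failed: target jerk unreachable (amp > 1e6)")
  }
  root <- stats::uniroot(g, c(0, hi), tol = hi * 1e-6)
  amp <- root$root
  achieved <- mean_jerk_at_amp(minjerk, amp, noisew, pipeline_args)
  if (abs(achieved - target_jerk_at_half) > tol * target_jerk_at_half) {
    stopf("calibration failed: achieved %.4g vs target %.4g",
          achieved, target_jerk_at_half)
  }
  out$amp_scale <- amp / 0.5
  out$achieved <- achieved
  class(out) <- "noise_calibration"
  out
}

#' @export
print.noise_calibration <- function(x, ...) {
  cat(sprintf(paste0(
    "Noise calibration: amp_scale = %.4g deg/SD (fwhm %.3g s, taper %.3g s)\n",
    "  mean jerk at SD = 0.5: %.4g deg/s^3 (target %.4g, baseline %.4g)\n"),
    x$amp_scale, x$fwhm, x$taper_tau, x$achieved, x$target, x$baseline))
  invisible(x)
}

#' Generate the jerk-graded stimulus condition set
#'
#' Builds one synthesized trajectory per noise amplitude on the SD grid
#' (default `0, 0.5, ..., 4.0`, nine conditions): condition 1 is the
#' minimum-jerk trajectory itself (`sd = 0`, bit-identical), the rest add
#' endpoint-constrained smooth noise of increasing amplitude.  The realized
#' average absolute jerk of every condition is measured with
#' [jerk_pipeline()] and stored alongside.
#'
#' @param x_i,x_f,d Movement parameters (deg, deg, s) of the reference
#'   minimum-jerk trajectory; defaults are the robot-hand grasp
#'   `161.4 -> 96.9` deg in 0.4 s.
#' @param rate Sampling rate, Hz.
#' @param sd_grid Increasing vector of SD amplitudes starting at 0.
#' @param calibration A `noise_calibration` from [calibrate_noise_units()],
#'   or `NULL` to calibrate now against `target_jerk_at_half`.
#' @param target_jerk_at_half,fwhm,taper_tau,n_draws Passed to
#'   [calibrate_noise_units()] when `calibration` is `NULL`.
#' @param seed Master seed; per-condition seeds are derived from it.
#' @param pipeline_args Arguments for [jerk_pipeline()] used for the
#'   realized-jerk measurement (and calibration).
#' @return An object of class `condition_set`: list with `conditions` (data
#'   frame `condition`, `sd`, `seed`, `realized_jerk`), `trajectories`
#'   (list of [joint_trajectory]), `calibration`, `spec`.
#' @examples
#' \donttest{
#' cs <- generate_condition_set(seed = 7, n_draws = 50)
#' cs$conditions
#' }
#' @export
generate_condition_set <- function(x_i = 161.4, x_f = 96.9, d = 0.4,
                                   rate = 120,
                                   sd_grid = c(0, seq(0.5, 4, by = 0.5)),
                                   calibration = NULL,
                                   target_jerk_at_half = 0.5e5,
                                   fwhm = 0.05, taper_tau = NULL,
                                   n_draws = 200, seed = 1L,
                                   pipeline_args = list()) {
  if (sd_grid[1] != 0) stopf("sd_grid must start at 0")
  if (any(diff(sd_grid) <= 0)) stopf("sd_grid must be strictly increasing")
  minjerk <- minimum_jerk_trajectory(x_i, x_f, d, rate)
  if (is.null(calibration)) {
    calibration <- calibrate_noise_units(
      minjerk, target_jerk_at_half, fwhm = fwhm, taper_tau = taper_tau,
      n_draws = n_draws, seed = seed, pipeline_args = pipeline_args)
  }
  stopifnot(inherits(calibration, "noise_calibration"))
  k <- length(sd_grid)
  seeds <- derive_seeds(seed + 1L, k)
  trajectories <- vector("list", k)
  realized <- numeric(k)
  for (i in seq_len(k)) {
    spec <- smooth_noise_spec(sd = sd_grid[i], fwhm = calibration$fwhm,
                              amp_scale = max(calibration$amp_scale,
                                              .Machine$double.xmin),
                              taper_tau = calibration$taper_tau,
                              seed = seeds[i])
    trajectories[[i]] <- synthesize_trajectory(minjerk, spec)
    realized[i] <- do.call(jerk_pipeline,
                           c(list(trajectories[[i]]), pipeline_args))
  }
  structure(list(
    conditions = data.frame(condition = seq_len(k), sd = sd_grid,
                            seed = seeds, realized_jerk = realized),
    trajectories = trajectories,
    calibration = calibration,
    spec = list(x_i = x_i, x_f = x_f, d = d, rate = rate,
                seed = as.integer(seed), pipeline_args = pipeline_args)),
    class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat(sprintf("Condition set: %d jerk-graded trajectories (%g -> %g deg, %g s at %g Hz)\n",
              nrow(x$conditions), x$spec$x_i, x$spec$x_f, x$spec$d,
              x$spec$rate))
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

#' @export
plot.condition_set <- function(x, ...) {
  k <- length(x$trajectories)
  cols <- grDevices::hcl.colors(k, "Zissou 1")
  plot(x$trajectories[[k]], col = cols[k], ...)
  for (i in seq_len(k - 1L)) {
    graphics::lines(x$trajectories[[i]]$t, x$trajectories[[i]]$theta,
                    col = cols[i])
  }
  invisible(x)
}

#' Write or read a condition set
#'
#' One `condition_<i>.csv` trajectory file per condition plus a
#' `manifest.json` recording the SD grid, seeds, calibration constants and
#' realized jerks.
#'
#' @param cs A `condition_set`.
#' @param dir Output directory (created if needed).
#' @return `write_condition_set()` returns `dir` invisibly;
#'   `read_condition_set()` a `condition_set` (without re-running
#'   calibration).
#' @export
write_condition_set <- function(cs, dir) {
  stopifnot(inherits(cs, "condition_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cs$trajectories)) {
    write_trajectory(cs$trajectories[[i]],
                     file.path(dir, sprintf("condition_%02d.csv", i)))
  }
  manifest <- list(conditions = cs$conditions,
                   calibration = unclass(cs$calibration),
                   spec = cs$spec)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_condition_set
#' @export
read_condition_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  k <- nrow(manifest$conditions)
  trajectories <- lapply(seq_len(k), function(i) {
    read_trajectory(file.path(dir, sprintf("condition_%02d.csv", i)))
  })
  calibration <- manifest$calibration
  class(calibration) <- "noise_calibration"
  structure(list(conditions = manifest$conditions,
                 trajectories = trajectories,
                 calibration = calibration,
                 spec = manifest$spec),
            class = "condition_set")
}
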