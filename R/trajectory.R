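#' Uniformly sampled joint-angle trajectory
#'
#' Container for a single-joint angular trajectory sampled on a uniform time
#' grid, the basic kinematic object of the package.  Angles are in degrees
#' and time in seconds throughout.
#'
#' @param t Numeric vector of time samples in seconds, uniformly spaced and
#'   increasing.
#' @param theta Numeric vector of joint angles in degrees, one per sample.
#' @param rate Sampling rate in Hz.  If omitted it is inferred from `t` and
#'   validated against the sample spacing.
#'
#' @return An object of class `joint_trajectory`: a list with elements `t`,
#'   `theta` and `rate`.
#' @examples
#' tr <- minimum_jerk_trajectory(161.4, 96.9, 0.4, rate = 120)
#' tr
#' @export
joint_trajectory <- function(t, theta, rate = NULL) {
  t <- as.numeric(t)
  theta <- as.numeric(theta)
  if (length(t) != length(theta)) {
    stopf("t and theta must have equal length (got %d and %d)",
          length(t), length(theta))
  }
  if (length(t) < 4L) stopf("a trajectory needs at least 4 samples")
  if (anyNA(t) || anyNA(theta)) stopf("trajectory contains NA values")
  dt <- diff(t)
  if (any(dt <= 0)) stopf("time samples must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9) {
    stopf("time samples are not uniformly spaced (spread %.3g s)",
          max(dt) - min(dt))
  }
  h <- mean(dt)
  if (is.null(rate)) rate <- 1 / h
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stopf("rate must be a positive scalar")
  }
  if (abs(1 / rate - h) > 1e-9) {
    stopf("rate (%.6g Hz) inconsistent with sample spacing (%.6g s)", rate, h)
  }
  structure(list(t = t, theta = theta, rate = rate),
            class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat(sprintf(
    "Joint-angle trajectory: %d samples at %g Hz over %.4g s, %.4g to %.4g deg\n",
    length(x$t), x$rate, x$t[length(x$t)] - x$t[1],
    x$theta[1], x$theta[length(x$theta)]))
  invisible(x)
}

#' @export
as.data.frame.joint_trajectory <- function(x, ...) {
  data.frame(t = x$t, theta = x$theta)
}

#' @export
length.joint_trajectory <- function(x) length(x$t)

#' @rdname joint_trajectory
#' @param x A `joint_trajectory`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.joint_trajectory <- function(x, ...) {
  graphics::plot(x$t, x$theta, type = "l", xlab = "time (s)",
                 ylab = "joint angle (deg)", ...)
  invisible(x)
}

#' Minimum-jerk point-to-point trajectory
#'
#' Generates the quintic-polynomial movement from `x_i` to `x_f` in `d`
#' seconds that minimizes integrated squared jerk under zero endpoint
#' velocity and acceleration:
#' \deqn{\theta(t) = x_i + (x_f - x_i)\,[10 (t/d)^3 - 15 (t/d)^4 + 6 (t/d)^5].}
#'
#' @param x_i Initial joint angle, degrees.
#' @param x_f Final joint angle, degrees.  `x_i == x_f` yields the constant
#'   (zero-motion) trajectory.
#' @param d Movement duration in seconds; must be positive.
#' @param rate Sampling rate in Hz.  The closed interval `[0, d]` is sampled,
#'   so `d * rate` must be a whole number of sampling intervals.
#'
#' @return A [joint_trajectory] with `theta[1] == x_i` and the last sample
#'   exactly `x_f`.
#' @examples
#' tr <- minimum_jerk_trajectory(161.4, 96.9, 0.4, rate = 120)
#' range(tr$theta)
#' @export
minimum_jerk_trajectory <- function(x_i, x_f, d, rate = 120) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0) {
    stopf("movement duration d must be a positive scalar")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stopf("rate must be a positive scalar")
  }
  if (rate < 2 / d) stopf("rate must be at least 2/d to resolve the movement")
  n_int <- d * rate
  if (abs(n_int - round(n_int)) > 1e-9) {
    stopf("d * rate must be an integer number of sampling intervals (got %.6g)",
          n_int)
  }
  n <- as.integer(round(n_int)) + 1L
  t <- seq.int(0L, n - 1L) / rate
  s <- t / d
  theta <- x_i + (x_f - x_i) * (10 * s^3 - 15 * s^4 + 6 * s^5)
  theta[1L] <- x_i
  theta[n] <- x_f
  joint_trajectory(t, theta, rate)
}

#' Closed-form average absolute jerk of a minimum-jerk movement
#'
#' Time average of the absolute third derivative of the quintic
#' minimum-jerk trajectory over its full duration,
#' \eqn{40 |x_f - x_i| / (\sqrt{3}\, d^3)} in deg/s^3.  Serves as the
#' analytic reference for the sampled metric.
#'
#' @inheritParams minimum_jerk_trajectory
#' @return Average absolute jerk in deg/s^3.
#' @examples
#' minimum_jerk_avg_abs_jerk(161.4, 96.9, 0.4)  # approx 2.33e4
#' @export
minimum_jerk_avg_abs_jerk <- function(x_i, x_f, d) {
  if (d <= 0) stopf("movement duration d must be positive")
  40 * abs(x_f - x_i) / (sqrt(3) * d^3)
}

#' Read or write a trajectory as CSV
#'
#' Plain CSV with header `t,theta`; the sampling rate is inferred from `t`
#' and validated on read.
#'
#' @param traj A [joint_trajectory].
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a [joint_trajectory].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "joint_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t", "theta") %in% names(df))) {
    stopf("trajectory CSV must have columns t and theta")
  }
  joint_trajectory(df$t, df$theta)
}
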