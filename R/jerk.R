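# Smoothness metric and the measurement chain around it: numerical third
# derivative, zero-phase low-pass filtering, movement segmentation, and
# joint-angle extraction from motion-capture markers.

#' Movement segment
#'
#' Onset/offset pair delimiting the moving part of a trajectory, in seconds.
#'
#' @param t0 Onset time, s.
#' @param t_end Offset time, s; must exceed `t0`.
#' @return An object of class `movement_segment`.
#' @export
movement_segment <- function(t0, t_end) {
  if (!is.numeric(t0) || !is.numeric(t_end) || t0 >= t_end) {
    stopf("movement segment requires t0 < t_end")
  }
  structure(list(t0 = t0, t_end = t_end), class = "movement_segment")
}

#' @export
print.movement_segment <- function(x, ...) {
  cat(sprintf("Movement segment: %.4g s to %.4g s (%.4g s)\n",
              x$t0, x$t_end, x$t_end - x$t0))
  invisible(x)
}

# Third time derivative on a uniform grid.  Central five-point stencil in
# the interior; second-order one-sided stencils at the two samples on each
# edge (falls back to the first-order four-point stencil when only four
# samples are available).
third_derivative <- function(theta, h) {
  n <- length(theta)
  if (n < 4L) stopf("third derivative needs at least 4 samples")
  j <- numeric(n)
  if (n >= 5L) {
    i <- 3:(n - 2L)
    j[i] <- (theta[i + 2L] - 2 * theta[i + 1L] + 2 * theta[i - 1L] -
               theta[i - 2L]) / (2 * h^3)
    j[1L] <- (-2.5 * theta[1L] + 9 * theta[2L] - 12 * theta[3L] +
                7 * theta[4L] - 1.5 * theta[5L]) / h^3
    j[2L] <- j[1L]
    j[n] <- (2.5 * theta[n] - 9 * theta[n - 1L] + 12 * theta[n - 2L] -
               7 * theta[n - 3L] + 1.5 * theta[n - 4L]) / h^3
    j[n - 1L] <- j[n]
  } else {
    fd <- (theta[4L] - 3 * theta[3L] + 3 * theta[2L] - theta[1L]) / h^3
    j[] <- fd
  }
  j
}

segment_index <- function(traj, segment) {
  if (is.null(segment)) return(seq_along(traj$t))
  stopifnot(inherits(segment, "movement_segment"))
  eps <- 1e-9
  if (segment$t0 < traj$t[1] - eps ||
      segment$t_end > traj$t[length(traj$t)] + eps) {
    stopf("segment [%.4g, %.4g] lies outside the trajectory span [%.4g, %.4g]",
          segment$t0, segment$t_end, traj$t[1], traj$t[length(traj$t)])
  }
  idx <- which(traj$t >= segment$t0 - eps & traj$t <= segment$t_end + eps)
  if (length(idx) < 4L) stopf("segment spans fewer than 4 samples")
  idx
}

#' Average absolute jerk of a trajectory segment
#'
#' The smoothness statistic: the mean over the movement of the absolute
#' third time derivative of the joint angle,
#' \deqn{\frac{1}{T}\sum_{t = t_0}^{T} \left| \frac{d^3\theta(t)}{dt^3} \right|,}
#' with the derivative estimated by finite differences on the sampling grid
#' (central five-point stencil in the interior, one-sided at the edges).
#'
#' @param traj A [joint_trajectory].
#' @param segment Optional [movement_segment] restricting the average to the
#'   moving part; default uses the whole trajectory.  Must span at least 4
#'   samples.
#' @return Average absolute jerk in deg/s^3 (non-negative; zero for any
#'   locally quadratic trajectory).
#' @examples
#' tr <- minimum_jerk_trajectory(161.4, 96.9, 0.4, rate = 120)
#' average_absolute_jerk(tr)
#' minimum_jerk_avg_abs_jerk(161.4, 96.9, 0.4)  # analytic reference
#' @export
average_absolute_jerk <- function(traj, segment = NULL) {
  stopifnot(inherits(traj, "joint_trajectory"))
  idx <- segment_index(traj, segment)
  j <- third_derivative(traj$theta[idx], 1 / traj$rate)
  mean(abs(j))
}

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward (zero phase delay) Butterworth filtering of a
#' joint-angle trajectory, the standard conditioning step before numerical
#' differentiation of motion-capture signals.
#'
#' @param traj A [joint_trajectory].
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist frequency.
#' @param order Filter order; default 5.
#' @return A filtered [joint_trajectory] on the same time grid.
#' @export
lowpass_zero_phase <- function(traj, cutoff = 10, order = 5) {
  stopifnot(inherits(traj, "joint_trajectory"))
  nyq <- traj$rate / 2
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= nyq) {
    stopf("cutoff must lie in (0, Nyquist) = (0, %g) Hz", nyq)
  }
  if (order < 1) stopf("order must be a positive integer")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  theta <- filtfilt_padded(bf, traj$theta, padlen = 3L * (order + 1L))
  joint_trajectory(traj$t, theta, traj$rate)
}

# Forward-backward filtering with odd-reflection end padding and DC-offset
# removal before each pass (the filter has unit DC gain, so subtracting the
# leading value suppresses the zero-state step transient).  Constants pass
# through exactly and phase delay cancels.
filtfilt_padded <- function(bf, x, padlen) {
  n <- length(x)
  L <- min(n - 1L, padlen)
  ext <- c(2 * x[1L] - x[(L + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - L)])
  one_pass <- function(z) {
    z0 <- z[1L]
    as.numeric(signal::filter(bf, z - z0)) + z0
  }
  y <- one_pass(ext)
  y <- rev(one_pass(rev(y)))
  y[(L + 1L):(L + n)]
}

#' Detect movement onset and offset by a velocity threshold
#'
#' Automates start/end marking of a movement: onset is the first time the
#' absolute angular velocity exceeds `threshold_frac` times its peak, offset
#' the last such time.
#'
#' @param traj A [joint_trajectory].
#' @param threshold_frac Fraction of peak absolute velocity; default 0.05.
#' @return A [movement_segment].
#' @export
detect_movement_bounds <- function(traj, threshold_frac = 0.05) {
  stopifnot(inherits(traj, "joint_trajectory"))
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stopf("threshold_frac must lie in (0, 1)")
  }
  h <- 1 / traj$rate
  n <- length(traj$theta)
  v <- numeric(n)
  i <- 2:(n - 1L)
  v[i] <- (traj$theta[i + 1L] - traj$theta[i - 1L]) / (2 * h)
  v[1L] <- (traj$theta[2L] - traj$theta[1L]) / h
  v[n] <- (traj$theta[n] - traj$theta[n - 1L]) / h
  vmax <- max(abs(v))
  scale <- max(1, max(abs(traj$theta)))
  if (vmax <= 1e-9 * scale) {
    stopf("no movement detected: peak velocity is at the numerical noise floor")
  }
  above <- which(abs(v) > threshold_frac * vmax)
  movement_segment(traj$t[above[1L]], traj$t[above[length(above)]])
}

#' Marker frame series
#'
#' Per-sample 3-D positions of the three hand markers used for joint-angle
#' extraction: the proximal interphalangeal joint (`PIP`), the
#' metacarpophalangeal joint (`MPjoint`) and the metacarpal bone (`MPbone`).
#'
#' @param t Time samples, seconds.
#' @param positions Data frame or matrix with columns `<marker>_x`,
#'   `<marker>_y`, `<marker>_z` for each of the three markers.
#' @return An object of class `marker_frames`.
#' @export
marker_frames <- function(t, positions) {
  positions <- as.data.frame(positions)
  need <- as.vector(outer(c("PIP", "MPjoint", "MPbone"), c("x", "y", "z"),
                          paste, sep = "_"))
  missing <- setdiff(need, names(positions))
  if (length(missing)) {
    stopf("marker columns missing: %s", paste(missing, collapse = ", "))
  }
  if (length(t) != nrow(positions)) stopf("t and positions lengths differ")
  if (anyNA(positions[need])) stopf("marker positions contain NA")
  structure(list(t = as.numeric(t), positions = positions[need]),
            class = "marker_frames")
}

#' @rdname marker_frames
#' @param path CSV path with header `t,<marker>_{x,y,z}`.
#' @export
read_marker_frames <- function(path) {
  df <- utils::read.csv(path)
  if (!"t" %in% names(df)) stopf("marker CSV must have a t column")
  marker_frames(df$t, df[setdiff(names(df), "t")])
}

#' Joint angle from marker triplets
#'
#' Computes the MP-joint flexion angle per frame as the angle at the
#' `MPjoint` marker between the vectors pointing to `MPbone` and to `PIP`
#' (in degrees, in `[0, 180]`).
#'
#' @param frames A [marker_frames] series.
#' @return A [joint_trajectory] of the MP-joint angle.
#' @export
joint_angle_from_markers <- function(frames) {
  stopifnot(inherits(frames, "marker_frames"))
  p <- frames$positions
  v1 <- cbind(p$PIP_x - p$MPjoint_x, p$PIP_y - p$MPjoint_y,
              p$PIP_z - p$MPjoint_z)
  v2 <- cbind(p$MPbone_x - p$MPjoint_x, p$MPbone_y - p$MPjoint_y,
              p$MPbone_z - p$MPjoint_z)
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  bad <- which(n1 < 1e-12 | n2 < 1e-12)
  if (length(bad)) {
    stopf("degenerate marker geometry (coincident markers) at frame %d",
          bad[1L])
  }
  cosang <- rowSums(v1 * v2) / (n1 * n2)
  cosang <- pmin(1, pmax(-1, cosang))
  joint_trajectory(frames$t, acos(cosang) * 180 / pi)
}

#' Full jerk measurement chain
#'
#' Replicates the processing applied to recorded and synthesized movements
#' before the smoothness statistic is taken: optional static-hold padding,
#' zero-phase low-pass filtering, movement segmentation, then
#' [average_absolute_jerk()] over the segment.
#'
#' @param traj A [joint_trajectory] containing just the movement.
#' @param pre_hold,post_hold Static hold durations (s) appended before and
#'   after the movement prior to filtering, emulating the recording context;
#'   defaults 0.8 s each.
#' @param cutoff,order Low-pass filter settings (Hz, filter order); set
#'   `cutoff = NULL` to skip filtering.
#' @param segment `"motion"` (default) measures over the known motion
#'   window; `"detect"` segments by the velocity threshold
#'   `threshold_frac`; or supply a [movement_segment] on the padded time
#'   axis.
#' @param threshold_frac Velocity threshold fraction for `segment = "detect"`.
#' @return Average absolute jerk in deg/s^3.
#' @examples
#' tr <- minimum_jerk_trajectory(161.4, 96.9, 0.4, rate = 120)
#' jerk_pipeline(tr)                 # filtered, as recorded data are treated
#' jerk_pipeline(tr, cutoff = NULL)  # unfiltered variant
#' @export
jerk_pipeline <- function(traj, pre_hold = 0.8, post_hold = 0.8,
                          cutoff = 10, order = 5,
                          segment = c("motion", "detect"),
                          threshold_frac = 0.05) {
  stopifnot(inherits(traj, "joint_trajectory"))
  padded <- assemble_animation_cycle(traj, pre_hold, post_hold)
  motion <- movement_segment(pre_hold, pre_hold + traj$t[length(traj$t)] -
                               traj$t[1])
  if (!is.null(cutoff)) padded <- lowpass_zero_phase(padded, cutoff, order)
  seg <- if (inherits(segment, "movement_segment")) {
    segment
  } else {
    segment <- match.arg(segment)
    if (segment == "detect") {
      detect_movement_bounds(padded, threshold_frac)
    } else {
      motion
    }
  }
  average_absolute_jerk(padded, seg)
}
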