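# Shared fixtures and independent oracles used across the test files.

hack_xi <- 161.4
hack_xf <- 96.9
hack_d <- 0.4

hack_minjerk <- function(rate = 120) {
  minimum_jerk_trajectory(hack_xi, hack_xf, hack_d, rate)
}

# Memoized calibration so the Monte-Carlo root-find runs once per session.
.fixture_env <- new.env(parent = emptyenv())

calibrated_set <- function() {
  if (is.null(.fixture_env$cs)) {
    .fixture_env$cal <- calibrate_noise_units(hack_minjerk(), 0.5e5,
                                              seed = 101)
    .fixture_env$cs <- generate_condition_set(seed = 202,
                                              calibration = .fixture_env$cal)
  }
  .fixture_env$cs
}

calibration_fixture <- function() {
  calibrated_set()
  .fixture_env$cal
}

# Independent angle oracle: plain arccos of the normalized dot product.
angle_oracle <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
}

# Numerical-quadrature oracle for the average |third derivative| of the
# quintic minimum-jerk polynomial (independent of the package's stencils).
quadrature_avg_jerk <- function(delta, d, n = 2e5) {
  s <- seq(0, 1, length.out = n)
  j <- abs(delta / d^3 * (60 - 360 * s + 360 * s^2))
  mean(j)
}

# Brute-force Bradley-Terry likelihood for small k on the simplex.
bt_loglik_oracle <- function(p, tab) {
  ll <- 0
  k <- nrow(tab)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && tab[i, j] > 0) {
        ll <- ll + tab[i, j] * log(p[i] / (p[i] + p[j]))
      }
    }
  }
  ll
}

# Closed-form log evidence of the linear-Gaussian model y = X beta + eps,
# beta ~ N(m0, V0), eps ~ N(0, s2 I): y ~ N(X m0, X V0 X' + s2 I).
conjugate_logml <- function(x, y, m0, V0, s2) {
  X <- cbind(1, x)
  S <- X %*% V0 %*% t(X) + s2 * diag(length(y))
  r <- y - as.numeric(X %*% m0)
  as.numeric(-0.5 * (length(y) * log(2 * pi) +
                       determinant(S, logarithm = TRUE)$modulus +
                       t(r) %*% solve(S, r)))
}

# Jerk-like abscissa and latent truth curves used in model-recovery tests:
# six conditions inside the analysis range (noise SD < 3.0), preferences on
# the Bradley-Terry scale (~0.1), transitions inside the allowed low-jerk
# region (jerk at SD < 1.5).
recovery_x <- c(22000, 50000, 90000, 130000, 170000, 210000)
recovery_trans_hi <- 130000

recovery_truth <- function(kind) {
  x0 <- min(recovery_x)
  span <- diff(range(recovery_x))
  trans <- 50000
  rise <- trans - x0
  switch(kind,
         A = pref_model("A", c(0.1 * (1 + x0 / span), -0.1 / span)),
         B = pref_model("B", c(0.1 * (1 + 1.5 * x0 / span), -0.15 / span,
                               trans)),
         C = pref_model("C", c(0.1 * (1 - 0.2 * trans / rise), 0.02 / rise,
                               trans)))
}
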