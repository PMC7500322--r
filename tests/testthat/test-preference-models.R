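test_that("the three model shapes evaluate exactly and continuously", {
  # constant special case of the linear model
  a <- pref_model("A", c(1, 0))
  expect_equal(predict(a, c(0, 10, 1e5)), rep(1, 3))

  # flattened model: both branches agree at the transition
  b <- pref_model("B", c(0.2, -2e-6, 5e4))
  expect_equal(predict(b, 5e4), 0.2 - 2e-6 * 5e4)
  expect_equal(predict(b, 5e4 - 1e-9), predict(b, 5e4 + 1e-9),
               tolerance = 1e-12)
  expect_equal(predict(b, 9e4), predict(b, 5e4))  # flat beyond

  # reversed model: f(2 c2) = c0 by the reflection identity
  cc <- pref_model("C", c(0.1, 3e-6, 4e4))
  expect_equal(predict(cc, 2 * 4e4), 0.1)
  expect_equal(predict(cc, 4e4 - 1e-9), predict(cc, 4e4 + 1e-9),
               tolerance = 1e-12)
  # slope flips sign at the transition
  eps <- 1
  slope_lo <- (predict(cc, 4e4) - predict(cc, 4e4 - eps)) / eps
  slope_hi <- (predict(cc, 4e4 + eps) - predict(cc, 4e4)) / eps
  expect_equal(slope_lo, -slope_hi, tolerance = 1e-9)

  expect_error(pref_model("D", c(1, 2)), "one of")
  expect_error(pref_model("B", c(1, 2)), "3 coefficients")
})

test_that("the Gaussian observation log-likelihood matches an independent sum", {
  m <- pref_model("A", c(0.5, -0.01))
  x <- 1:6
  y <- predict(m, x)
  dat <- fit_dataset(x, y)
  expect_equal(pref_loglik(m, 1, dat), -6 / 2 * log(2 * pi))

  set.seed(8)
  y2 <- y + rnorm(6, 0, 0.1)
  dat2 <- fit_dataset(x, y2)
  oracle <- sum(vapply(1:6, function(i) {
    -0.5 * log(2 * pi * 0.1^2) - (y2[i] - predict(m, x[i]))^2 / (2 * 0.1^2)
  }, numeric(1)))
  expect_equal(pref_loglik(m, 0.1, dat2), oracle, tolerance = 1e-12)

  # masked points do not contribute
  dat3 <- fit_dataset(c(x, 100), c(y2, 99), mask = c(rep(TRUE, 6), FALSE))
  expect_equal(pref_loglik(m, 0.1, dat3), pref_loglik(m, 0.1, dat2))
})

test_that("the SD-based analysis mask excludes high-noise conditions", {
  dat <- fit_dataset(1:9, 9:1, sd = c(0, seq(0.5, 4, 0.5)))
  expect_equal(sum(dat$mask), 6)
  expect_false(any(dat$mask[7:9]))
  expect_error(fit_dataset(1:3, 1:3, mask = rep(FALSE, 3)), "excludes")
})

test_that("posterior sampling recovers generating parameters and the prior", {
  x <- seq_len(7)
  set.seed(21)
  y <- 0.5 - 0.04 * x + rnorm(7, 0, 0.01)
  dat <- fit_dataset(x, y)
  pr <- pref_priors(dat)
  post <- sample_posterior("A", pr, dat, n_iter = 6000, burn = 1500,
                           seed = 22)
  sl <- post$draws[, "a1"]
  expect_lt(abs(mean(sl) - (-0.04)), 3 * sd(sl))
  expect_true(all(post$rhat < 1.2, na.rm = TRUE))

  # likelihood off: prior moments recovered within Monte-Carlo error
  prior_only <- sample_posterior("A", pr, NULL, n_iter = 8000, burn = 1000,
                                 seed = 23)
  a0 <- prior_only$draws[, "a0"]
  expect_lt(abs(mean(a0) - pr$intercept[["mean"]]),
            5 * pr$intercept[["sd"]] / sqrt(prior_only$ess[["a0"]]))
  expect_lt(abs(sd(a0) / pr$intercept[["sd"]] - 1), 0.2)
  sig <- prior_only$draws[, "sigma"]
  expect_lt(abs(mean(sig) / (pr$noise$scale * sqrt(2 / pi)) - 1), 0.2)

  # determinism under a fixed seed
  p1 <- sample_posterior("A", pr, dat, n_iter = 1500, burn = 400, seed = 5)
  p2 <- sample_posterior("A", pr, dat, n_iter = 1500, burn = 400, seed = 5)
  expect_identical(p1$draws, p2$draws)
})

test_that("transition-point posteriors never escape their truncation bounds", {
  set.seed(31)
  x <- recovery_x
  y <- predict(recovery_truth("C"), x) + rnorm(length(x), 0, 0.005)
  dat <- fit_dataset(x, y)
  pr <- pref_priors(dat, transition_bounds = c(min(x), recovery_trans_hi))
  post <- sample_posterior("C", pr, dat, n_iter = 4000, burn = 1000,
                           seed = 32)
  tr <- post$draws[, "c2"]
  expect_true(all(tr >= min(x) & tr <= recovery_trans_hi))
})

test_that("marginal likelihoods match the conjugate closed form within 1%", {
  set.seed(41)
  x <- as.numeric(1:7)
  y <- 0.5 - 0.04 * x + rnorm(7, 0, 0.05)
  dat <- fit_dataset(x, y)
  pr <- pref_priors(dat, noise_fixed = 0.05)
  exact <- conjugate_logml(x, y,
                           c(pr$intercept[["mean"]], pr$slope[["mean"]]),
                           diag(c(pr$intercept[["sd"]],
                                  pr$slope[["sd"]])^2), 0.05^2)
  # the estimate agrees with the closed form within its reported MC error
  mls <- lapply(1:3, function(s) {
    marginal_likelihood("A", pr, dat, n_draws = 5e4, seed = s)
  })
  for (ml in mls) expect_lt(abs(ml$logml - exact), 3 * ml$se)
  # and a long run pins the evidence to within 1%
  long <- marginal_likelihood("A", pr, dat, n_draws = 2e5, seed = 4)
  expect_lt(abs(exp(long$logml - exact) - 1), 0.01)
  # stability across seeds within a few MC standard errors
  spread <- vapply(mls, function(m) m$logml, numeric(1))
  expect_lt(max(spread) - min(spread), 6 * max(vapply(mls, function(m) m$se,
                                                      numeric(1))))
})

test_that("Bayes factors obey identity, reciprocity and transitivity", {
  set.seed(51)
  x <- recovery_x
  y <- predict(recovery_truth("B"), x) + rnorm(length(x), 0, 0.005)
  dat <- fit_dataset(x, y)
  pr <- pref_priors(dat, transition_bounds = c(min(x), recovery_trans_hi))

  # same model, same data, same seed: BF exactly 1
  m1 <- marginal_likelihood("A", pr, dat, n_draws = 1e4, seed = 9)
  m2 <- marginal_likelihood("A", pr, dat, n_draws = 1e4, seed = 9)
  expect_identical(m1$logml, m2$logml)

  cmp <- compare_pref_models(dat, priors = pr, n_draws = 2e4, seed = 52)
  bf <- cmp$bf
  expect_equal(diag(bf), rep(1, 3), ignore_attr = TRUE)
  expect_equal(bf * t(bf), matrix(1, 3, 3), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(log(bf["A", "C"]),
               log(bf["A", "B"]) + log(bf["B", "C"]), tolerance = 1e-9)
})

test_that("Bayes-factor magnitudes map onto the conventional evidence labels", {
  expect_equal(interpret_bayes_factor(78726), "decisive")
  expect_equal(interpret_bayes_factor(1.5), "barely worth mentioning")
  expect_equal(interpret_bayes_factor(1), "barely worth mentioning")
  expect_equal(interpret_bayes_factor(5.6), "substantial")
  expect_equal(interpret_bayes_factor(1 / 5.6), "substantial")
  expect_equal(interpret_bayes_factor(20), "strong")
  expect_equal(interpret_bayes_factor(50), "very strong")
  expect_error(interpret_bayes_factor(-2), "positive")
})

test_that("reciprocal Bayes factors are consistent after rounding", {
  # a reported pair like 8.3 vs 0.1 is the same comparison seen from both
  # sides: 1 / 8.3 = 0.12, which rounds to 0.1
  expect_equal(round(1 / 8.3, 1), 0.1)
  bfs <- bayes_factors(c(A = log(8.3), B = 0))
  expect_equal(bfs$bf["B", "A"], 1 / 8.3, tolerance = 1e-12)
})
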