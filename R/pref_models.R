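# Piecewise jerk-preference models and their Bayesian comparison.
#
# Three competing shapes for the relation between average absolute jerk x
# and Bradley-Terry preference f(x):
#   Model A (linear):    f(x) = a0 + a1 x
#   Model B (flattened): f(x) = b0 + b1 x        for x <  b2
#                        f(x) = b0 + b1 b2       otherwise
#   Model C (reversed):  f(x) = c0 + c1 x        for x <  c2
#                        f(x) = c0 - c1 x + 2 c1 c2  otherwise
# B and C are continuous at their transition points by construction.

model_coef_names <- function(kind) {
  switch(kind,
         A = c("a0", "a1"),
         B = c("b0", "b1", "b2"),
         C = c("c0", "c1", "c2"),
         stopf("unknown model kind '%s' (must be A, B or C)", kind))
}

#' Piecewise jerk-preference model
#'
#' Constructs one of the three preference profiles over average absolute
#' jerk: linear (`A`), flattened beyond a transition point (`B`), or
#' slope-reversed at a transition point (`C`).  Kinds B and C are
#' continuous at the transition.
#'
#' @param kind One of `"A"`, `"B"`, `"C"`.
#' @param coef Coefficient vector: `(a0, a1)` for A; `(b0, b1, b2)` for B
#'   and `(c0, c1, c2)` for C, where the third entry is the transition
#'   point on the jerk axis (deg/s^3) and slopes are preference per
#'   (deg/s^3).
#' @return An object of class `pref_model`.
#' @examples
#' m <- pref_model("C", c(0.1, 2e-6, 5e4))
#' predict(m, c(3e4, 5e4, 8e4))
#' @export
pref_model <- function(kind = c("A", "B", "C"), coef) {
  kind <- match.arg(kind)
  nm <- model_coef_names(kind)
  if (length(coef) != length(nm)) {
    stopf("model %s needs %d coefficients (%s)", kind, length(nm),
          paste(nm, collapse = ", "))
  }
  if (any(!is.finite(coef))) stopf("coefficients must be finite")
  coef <- stats::setNames(as.numeric(coef), nm)
  structure(list(kind = kind, coef = coef), class = "pref_model")
}

#' @export
print.pref_model <- function(x, ...) {
  cat(sprintf("Preference model %s: %s\n", x$kind,
              paste(sprintf("%s = %.4g", names(x$coef), x$coef),
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.pref_model <- function(object, ...) object$coef

# Effective abscissa: B clamps x at the transition, C reflects it.
effective_x <- function(kind, x, trans) {
  switch(kind,
         A = x,
         B = pmin(x, trans),
         C = ifelse(x < trans, x, 2 * trans - x))
}

#' @rdname pref_model
#' @param object A `pref_model`.
#' @param x Jerk values (deg/s^3) at which to evaluate the curve.
#' @param ... Unused.
#' @export
predict.pref_model <- function(object, x, ...) {
  cf <- object$coef
  trans <- if (object$kind == "A") Inf else cf[[3]]
  cf[[1]] + cf[[2]] * effective_x(object$kind, x, trans)
}

#' Jerk-preference dataset
#'
#' Pairs each condition's measured average absolute jerk with its fitted
#' Bradley-Terry preference, together with the inclusion mask used in the
#' model comparison (conditions with noise amplitude `SD >= 3.0` are
#' excluded from the analysis range).
#'
#' @param x Average absolute jerk per condition, deg/s^3.
#' @param y Bradley-Terry preference per condition.
#' @param sd Optional noise-amplitude grid values; used to build the
#'   default mask `sd < sd_max`.
#' @param mask Optional logical inclusion vector overriding the SD rule.
#' @param sd_max Exclusion threshold on `sd`; default 3.0.
#' @return An object of class `fit_dataset`.
#' @export
fit_dataset <- function(x, y, sd = NULL, mask = NULL, sd_max = 3.0) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (is.null(mask)) {
    mask <- if (is.null(sd)) rep(TRUE, length(x)) else sd < sd_max
  }
  if (length(mask) != length(x)) stopf("mask length must match data")
  if (!any(mask)) stopf("inclusion mask excludes every point")
  structure(list(x = as.numeric(x), y = as.numeric(y), sd = sd,
                 mask = as.logical(mask)),
            class = "fit_dataset")
}

#' @export
print.fit_dataset <- function(x, ...) {
  cat(sprintf("Jerk-preference dataset: %d conditions, %d in analysis range\n",
              length(x$x), sum(x$mask)))
  df <- data.frame(x = x$x, y = x$y, included = x$mask)
  if (!is.null(x$sd)) df <- cbind(sd = x$sd, df)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Gaussian observation log-likelihood of a preference model
#'
#' Sum of Gaussian log-densities of the included preference points around
#' the model curve: `y_i ~ Normal(f(x_i), noise_sd)` over points with
#' `mask = TRUE`.
#'
#' @param model A [pref_model].
#' @param noise_sd Observation noise standard deviation (> 0).
#' @param data A [fit_dataset].
#' @return Log-likelihood (scalar).
#' @export
pref_loglik <- function(model, noise_sd, data) {
  stopifnot(inherits(model, "pref_model"), inherits(data, "fit_dataset"))
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  xm <- data$x[data$mask]
  ym <- data$y[data$mask]
  sum(stats::dnorm(ym, predict(model, xm), noise_sd, log = TRUE))
}

#' Priors for the preference-model coefficients
#'
#' Relatively weak normal priors on intercept and slope, a truncated-normal
#' prior on the transition point restricted to the low-jerk region
#' (jerk values of conditions with `SD < 1.5`), and a half-normal prior on
#' the observation noise.  Defaults scale with the data: intercept
#' `N(mean(y), scale * sd(y))`, slope `N(0, scale * sd(y)/sd(x))`,
#' transition `N(midpoint, scale * width)` truncated to
#' `transition_bounds`, noise `half-N(scale * sd(y))`.
#'
#' @param data A [fit_dataset] (masked points set the scales).
#' @param transition_bounds Length-2 vector: allowed transition-point
#'   interval on the jerk axis.  Defaults to the span of the included `x`
#'   values; pass the jerk value of the `SD = 1.5` condition as the upper
#'   bound to apply the low-jerk restriction.
#' @param scale Prior breadth multiplier; default 10 ("relatively weak").
#' @param noise_fixed Optional fixed observation noise SD; when given, the
#'   noise is not a free parameter.
#' @return An object of class `pref_priors`.
#' @export
pref_priors <- function(data, transition_bounds = NULL, scale = 10,
                        noise_fixed = NULL) {
  stopifnot(inherits(data, "fit_dataset"))
  if (scale <= 0) stopf("prior scale must be positive")
  xm <- data$x[data$mask]
  ym <- data$y[data$mask]
  sx <- stats::sd(xm)
  sy <- stats::sd(ym)
  if (!is.finite(sx) || sx == 0 || !is.finite(sy) || sy == 0) {
    stopf("degenerate data: zero spread in x or y")
  }
  if (is.null(transition_bounds)) transition_bounds <- range(xm)
  if (length(transition_bounds) != 2 ||
      transition_bounds[1] >= transition_bounds[2]) {
    stopf("transition_bounds must be an increasing length-2 interval")
  }
  if (!is.null(noise_fixed) && noise_fixed <= 0) {
    stopf("noise_fixed must be positive")
  }
  structure(list(
    intercept = c(mean = mean(ym), sd = scale * sy),
    slope = c(mean = 0, sd = scale * sy / sx),
    transition = list(mean = mean(transition_bounds),
                      sd = scale * diff(transition_bounds),
                      lower = transition_bounds[1],
                      upper = transition_bounds[2]),
    noise = list(scale = scale * sy, fixed = noise_fixed)),
    class = "pref_priors")
}

# ---- parameter-vector plumbing -------------------------------------------

param_names <- function(kind, priors) {
  nm <- model_coef_names(kind)
  if (is.null(priors$noise$fixed)) nm <- c(nm, "sigma")
  nm
}

# S draws from the prior; returns an S x p matrix.
prior_sample <- function(kind, priors, S, seed = NULL) {
  with_seed(seed, {
    draws <- cbind(
      stats::rnorm(S, priors$intercept[["mean"]], priors$intercept[["sd"]]),
      stats::rnorm(S, priors$slope[["mean"]], priors$slope[["sd"]]))
    if (kind != "A") {
      tr <- priors$transition
      plo <- stats::pnorm(tr$lower, tr$mean, tr$sd)
      phi <- stats::pnorm(tr$upper, tr$mean, tr$sd)
      u <- stats::runif(S, plo, phi)
      draws <- cbind(draws, stats::qnorm(u, tr$mean, tr$sd))
    }
    if (is.null(priors$noise$fixed)) {
      draws <- cbind(draws, abs(stats::rnorm(S, 0, priors$noise$scale)))
    }
    colnames(draws) <- param_names(kind, priors)
    draws
  })
}

# Log prior density for an S x p matrix of parameter values.
prior_logdens <- function(kind, priors, par) {
  lp <- stats::dnorm(par[, 1], priors$intercept[["mean"]],
                     priors$intercept[["sd"]], log = TRUE) +
    stats::dnorm(par[, 2], priors$slope[["mean"]], priors$slope[["sd"]],
                 log = TRUE)
  if (kind != "A") {
    tr <- priors$transition
    z <- log(stats::pnorm(tr$upper, tr$mean, tr$sd) -
               stats::pnorm(tr$lower, tr$mean, tr$sd))
    dtr <- stats::dnorm(par[, 3], tr$mean, tr$sd, log = TRUE) - z
    dtr[par[, 3] < tr$lower | par[, 3] > tr$upper] <- -Inf
    lp <- lp + dtr
  }
  if (is.null(priors$noise$fixed)) {
    s <- par[, ncol(par)]
    ds <- log(2) + stats::dnorm(s, 0, priors$noise$scale, log = TRUE)
    ds[s <= 0] <- -Inf
    lp <- lp + ds
  }
  lp
}

# Data log-likelihood for an S x p matrix of parameter values; data NULL
# (prior-only) gives 0.
data_loglik <- function(kind, priors, par, data) {
  if (is.null(data)) return(rep(0, nrow(par)))
  xm <- data$x[data$mask]
  ym <- data$y[data$mask]
  n <- length(xm)
  S <- nrow(par)
  X <- matrix(xm, S, n, byrow = TRUE)
  if (kind != "A") {
    trans <- par[, 3]
    Xe <- if (kind == "B") pmin(X, trans) else ifelse(X < trans, X,
                                                      2 * trans - X)
  } else {
    Xe <- X
  }
  F <- par[, 1] + par[, 2] * Xe
  ss <- rowSums((F - matrix(ym, S, n, byrow = TRUE))^2)
  sigma <- if (is.null(priors$noise$fixed)) par[, ncol(par)] else
    priors$noise$fixed
  ll <- -n / 2 * log(2 * pi) - n * log(sigma) - ss / (2 * sigma^2)
  ll[!is.finite(ll)] <- -Inf
  ll
}

# ---- posterior sampling ---------------------------------------------------

log_post <- function(kind, priors, par_row, data) {
  par <- matrix(par_row, nrow = 1)
  lp <- prior_logdens(kind, priors, par)
  if (!is.finite(lp)) return(-Inf)
  lp + data_loglik(kind, priors, par, data)
}

#' Posterior sampling for a preference model
#'
#' Componentwise adaptive random-walk Metropolis sampling of the model
#' coefficients (and the observation noise SD, unless fixed) under the
#' priors of [pref_priors()].  Proposal scales adapt during burn-in toward
#' a 30-45% acceptance rate; chains are thinned after burn-in.  With
#' `data = NULL` the likelihood is switched off and the sampler draws from
#' the prior (useful as a correctness check).
#'
#' @param kind Model kind, `"A"`, `"B"` or `"C"`.
#' @param priors A [pref_priors].
#' @param data A [fit_dataset], or `NULL` for prior-only sampling.
#' @param n_iter Iterations per chain after burn-in; default 20000.
#' @param burn Burn-in iterations; default 2000.
#' @param thin Thinning interval; default 6.
#' @param chains Number of chains; default 2.
#' @param seed RNG seed.
#' @return An object of class `pref_posterior`: `draws` (matrix of thinned
#'   post-burn-in samples, all chains stacked), `chain` (chain index per
#'   draw), `rhat` and `ess` per parameter, `accept` rate, plus the call
#'   settings.  A warning is raised if any split-R-hat exceeds 1.1.
#' @export
sample_posterior <- function(kind, priors, data, n_iter = 20000,
                             burn = 2000, thin = 6, chains = 2,
                             seed = NULL) {
  kind <- match.arg(kind, c("A", "B", "C"))
  stopifnot(inherits(priors, "pref_priors"))
  nm <- param_names(kind, priors)
  p <- length(nm)
  seeds <- derive_seeds(seed, chains)
  init_scales <- c(priors$intercept[["sd"]], priors$slope[["sd"]])
  if (kind != "A") {
    init_scales <- c(init_scales,
                     (priors$transition$upper - priors$transition$lower) / 4)
  }
  if (is.null(priors$noise$fixed)) {
    init_scales <- c(init_scales, priors$noise$scale)
  }
  run_chain <- function(cseed) {
    with_seed(cseed, {
      cur <- as.numeric(prior_sample(kind, priors, 1L))
      lp_cur <- log_post(kind, priors, cur, data)
      while (!is.finite(lp_cur)) {
        cur <- as.numeric(prior_sample(kind, priors, 1L))
        lp_cur <- log_post(kind, priors, cur, data)
      }
      step <- init_scales / 10
      total <- burn + n_iter
      keep <- matrix(NA_real_, ceiling(n_iter / thin), p)
      acc <- 0L
      prop_n <- 0L
      kept <- 0L
      for (it in seq_len(total)) {
        for (d in seq_len(p)) {
          cand <- cur
          cand[d] <- cand[d] + stats::rnorm(1L, 0, step[d])
          lp_cand <- log_post(kind, priors, cand, data)
          prop_n <- prop_n + 1L
          if (is.finite(lp_cand) &&
              log(stats::runif(1L)) < lp_cand - lp_cur) {
            cur <- cand
            lp_cur <- lp_cand
            acc <- acc + 1L
            if (it <= burn) step[d] <- step[d] * 1.02
          } else if (it <= burn) {
            step[d] <- step[d] / 1.01
          }
        }
        if (it > burn && (it - burn) %% thin == 0L) {
          kept <- kept + 1L
          keep[kept, ] <- cur
        }
      }
      list(draws = keep[seq_len(kept), , drop = FALSE],
           accept = acc / prop_n)
    })
  }
  res <- lapply(seeds, run_chain)
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  colnames(draws) <- nm
  chain <- rep(seq_len(chains), vapply(res, function(r) nrow(r$draws),
                                       integer(1)))
  rhat <- vapply(seq_len(p), function(d) {
    split_rhat(draws[, d], chain)
  }, numeric(1))
  ess <- vapply(seq_len(p), function(d) ess_acf(draws[, d]), numeric(1))
  names(rhat) <- names(ess) <- nm
  if (any(rhat > 1.1, na.rm = TRUE)) {
    warning(sprintf("possible non-convergence: split R-hat > 1.1 for %s",
                    paste(nm[rhat > 1.1], collapse = ", ")), call. = FALSE)
  }
  structure(list(draws = draws, chain = chain, kind = kind,
                 rhat = rhat, ess = ess,
                 accept = mean(vapply(res, `[[`, numeric(1), "accept")),
                 settings = list(n_iter = n_iter, burn = burn, thin = thin,
                                 chains = chains, seed = seed)),
            class = "pref_posterior")
}

# Split-chain potential scale reduction factor.
split_rhat <- function(x, chain) {
  halves <- unlist(lapply(unique(chain), function(cc) {
    xs <- x[chain == cc]
    h <- length(xs) %/% 2L
    list(xs[seq_len(h)], xs[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(h) h[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size from the initial-positive autocorrelation sum.
ess_acf <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r < 0.05) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' @export
print.pref_posterior <- function(x, ...) {
  cat(sprintf("Posterior for preference model %s: %d draws (%d chains)\n",
              x$kind, nrow(x$draws), x$settings$chains))
  sm <- cbind(mean = colMeans(x$draws), sd = apply(x$draws, 2, stats::sd),
              rhat = x$rhat, ess = round(x$ess))
  print(round(sm, 6))
  cat(sprintf("mean acceptance rate %.2f\n", x$accept))
  invisible(x)
}

#' @export
summary.pref_posterior <- function(object, ...) {
  q <- t(apply(object$draws, 2, stats::quantile,
               probs = c(0.025, 0.5, 0.975)))
  cbind(mean = colMeans(object$draws),
        sd = apply(object$draws, 2, stats::sd), q,
        rhat = object$rhat, ess = object$ess)
}

# ---- marginal likelihood --------------------------------------------------

#' Marginal likelihood of a preference model
#'
#' Estimates the log evidence `log integral L(theta) pi(theta) dtheta` by
#' Monte-Carlo integration over the prior, optionally refined by defensive
#' importance sampling: a second pass draws from an equal mixture of the
#' prior and an independence proposal moment-matched to the
#' likelihood-weighted first-pass draws (log-normal component for the noise
#' SD, truncated normal for the transition point).  All models here have at
#' most four free parameters, for which this direct integration is
#' accurate and fast.
#'
#' @inheritParams sample_posterior
#' @param n_draws Monte-Carlo draws per pass; default 1e5.
#' @param refine Run the importance-sampling refinement pass; default TRUE.
#' @return An object of class `marginal_likelihood`: `logml`, `se`
#'   (Monte-Carlo standard error on the log scale), `kind`, `n_draws`,
#'   `method`, and `post_mean` (importance-weighted posterior means).
#' @export
marginal_likelihood <- function(kind, priors, data, n_draws = 1e5,
                                refine = TRUE, seed = NULL) {
  kind <- match.arg(kind, c("A", "B", "C"))
  stopifnot(inherits(priors, "pref_priors"))
  if (priors$intercept[["sd"]] <= 0 || priors$slope[["sd"]] <= 0) {
    stopf("degenerate prior: non-positive scale")
  }
  seeds <- derive_seeds(seed, 2L)
  par1 <- prior_sample(kind, priors, n_draws, seeds[1])
  ll1 <- data_loglik(kind, priors, par1, data)
  if (all(ll1 == -Inf)) stopf("likelihood vanished on every prior draw")
  logml <- logsumexp(ll1) - log(n_draws)
  w1 <- exp(ll1 - max(ll1))
  se <- se_logmean(w1)
  method <- "prior-MC"
  post_mean <- colSums(par1 * w1) / sum(w1)
  if (refine) {
    prop <- moment_proposal(kind, priors, par1, w1)
    mix <- with_seed(seeds[2], mixture_sample(kind, priors, prop, n_draws))
    ll2 <- data_loglik(kind, priors, mix$par, data)
    lpi <- prior_logdens(kind, priors, mix$par)
    lg <- proposal_logdens(kind, priors, prop, mix$par)
    lq <- apply(cbind(lpi, lg), 1, logsumexp) - log(2)
    lw <- ll2 + lpi - lq
    keep <- is.finite(lpi)
    lw <- lw[keep]
    logml <- logsumexp(lw) - log(n_draws)
    w2 <- exp(lw - max(lw))
    se <- se_logmean(w2)
    post_mean <- colSums(mix$par[keep, , drop = FALSE] * w2) / sum(w2)
    method <- "prior-MC + importance refinement"
  }
  names(post_mean) <- param_names(kind, priors)
  structure(list(logml = logml, se = se, kind = kind, n_draws = n_draws,
                 method = method, post_mean = post_mean),
            class = "marginal_likelihood")
}

# MC standard error of log(mean(w)) from unnormalized weights.
se_logmean <- function(w) {
  n <- length(w)
  stats::sd(w) / (mean(w) * sqrt(n))
}

# Independence proposal moment-matched to likelihood-weighted draws.
moment_proposal <- function(kind, priors, par, w) {
  w <- w / sum(w)
  inflate <- 1.5
  wm <- function(v) sum(w * v)
  wsd <- function(v) {
    s <- sqrt(max(sum(w * (v - wm(v))^2), 0))
    max(s, 1e-12)
  }
  prop <- list(
    intercept = c(mean = wm(par[, 1]), sd = inflate * wsd(par[, 1])),
    slope = c(mean = wm(par[, 2]), sd = inflate * wsd(par[, 2])))
  if (kind != "A") {
    prop$transition <- list(mean = wm(par[, 3]),
                            sd = inflate * wsd(par[, 3]),
                            lower = priors$transition$lower,
                            upper = priors$transition$upper)
  }
  if (is.null(priors$noise$fixed)) {
    ls <- log(par[, ncol(par)])
    prop$lsigma <- c(mean = wm(ls), sd = inflate * wsd(ls))
  }
  prop
}

mixture_sample <- function(kind, priors, prop, S) {
  from_g <- stats::runif(S) < 0.5
  n_g <- sum(from_g)
  par <- prior_sample(kind, priors, S)
  if (n_g) {
    g <- cbind(stats::rnorm(n_g, prop$intercept[["mean"]],
                            prop$intercept[["sd"]]),
               stats::rnorm(n_g, prop$slope[["mean"]], prop$slope[["sd"]]))
    if (kind != "A") {
      tr <- prop$transition
      plo <- stats::pnorm(tr$lower, tr$mean, tr$sd)
      phi <- stats::pnorm(tr$upper, tr$mean, tr$sd)
      u <- stats::runif(n_g, plo, phi)
      g <- cbind(g, stats::qnorm(u, tr$mean, tr$sd))
    }
    if (is.null(priors$noise$fixed)) {
      g <- cbind(g, exp(stats::rnorm(n_g, prop$lsigma[["mean"]],
                                     prop$lsigma[["sd"]])))
    }
    par[from_g, ] <- g
  }
  list(par = par, from_g = from_g)
}

proposal_logdens <- function(kind, priors, prop, par) {
  lg <- stats::dnorm(par[, 1], prop$intercept[["mean"]],
                     prop$intercept[["sd"]], log = TRUE) +
    stats::dnorm(par[, 2], prop$slope[["mean"]], prop$slope[["sd"]],
                 log = TRUE)
  if (kind != "A") {
    tr <- prop$transition
    z <- log(stats::pnorm(tr$upper, tr$mean, tr$sd) -
               stats::pnorm(tr$lower, tr$mean, tr$sd))
    dtr <- stats::dnorm(par[, 3], tr$mean, tr$sd, log = TRUE) - z
    dtr[par[, 3] < tr$lower | par[, 3] > tr$upper] <- -Inf
    lg <- lg + dtr
  }
  if (is.null(priors$noise$fixed)) {
    s <- par[, ncol(par)]
    dls <- stats::dnorm(log(s), prop$lsigma[["mean"]], prop$lsigma[["sd"]],
                        log = TRUE) - log(s)
    dls[s <= 0] <- -Inf
    lg <- lg + dls
  }
  lg
}

#' @export
print.marginal_likelihood <- function(x, ...) {
  cat(sprintf("Model %s log marginal likelihood: %.4f (MC SE %.4f, %s, %d draws)\n",
              x$kind, x$logml, x$se, x$method, x$n_draws))
  invisible(x)
}

# ---- Bayes factors --------------------------------------------------------

#' Pairwise Bayes factors from marginal likelihoods
#'
#' Builds the Bayes-factor matrix `BF[i, j] = exp(logML_i - logML_j)`
#' together with verbal evidence labels.  Reciprocity
#' (`BF[i, j] * BF[j, i] = 1`) and transitivity hold by construction.
#'
#' @param logml Named numeric vector of log marginal likelihoods, or a list
#'   of [marginal_likelihood] objects.
#' @return An object of class `model_comparison`: `logml`, `bf` (matrix),
#'   `labels` (matrix of evidence labels for each ordered pair).
#' @export
bayes_factors <- function(logml) {
  if (is.list(logml)) {
    nm <- vapply(logml, function(m) m$kind, character(1))
    logml <- stats::setNames(vapply(logml, function(m) m$logml,
                                    numeric(1)), nm)
  }
  if (any(!is.finite(logml))) stopf("marginal likelihoods must be finite")
  if (is.null(names(logml))) names(logml) <- LETTERS[seq_along(logml)]
  bf <- exp(outer(logml, logml, "-"))
  labels <- matrix("", nrow(bf), ncol(bf), dimnames = dimnames(bf))
  for (i in seq_len(nrow(bf))) {
    for (j in seq_len(ncol(bf))) {
      labels[i, j] <- interpret_bayes_factor(bf[i, j])
    }
  }
  structure(list(logml = logml, bf = bf, labels = labels),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat("Bayesian model comparison\n")
  cat("log marginal likelihoods:\n")
  print(round(x$logml, 3))
  cat("Bayes factors (row over column):\n")
  print(signif(x$bf, digits))
  nm <- names(x$logml)
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i < j) {
        bf <- x$bf[i, j]
        dir <- if (bf >= 1) sprintf("%s over %s", nm[i], nm[j]) else
          sprintf("%s over %s", nm[j], nm[i])
        cat(sprintf("  %s vs. %s: BF = %.3g (evidence for %s: %s)\n",
                    nm[i], nm[j], bf, dir, x$labels[i, j]))
      }
    }
  }
  invisible(x)
}

#' Verbal interpretation of a Bayes factor
#'
#' Maps the magnitude `max(bf, 1/bf)` onto the conventional evidence
#' categories (half-decade bands): below 10^0.5 "barely worth mentioning",
#' then "substantial" (to 10), "strong" (to 10^1.5), "very strong"
#' (to 100) and "decisive" above 100.
#'
#' @param bf A positive Bayes factor.
#' @return Character evidence label.
#' @examples
#' interpret_bayes_factor(78726)  # "decisive"
#' interpret_bayes_factor(1.5)    # "barely worth mentioning"
#' @export
interpret_bayes_factor <- function(bf) {
  if (!is.numeric(bf) || length(bf) != 1L || is.na(bf) || bf <= 0) {
    stopf("bf must be a positive number")
  }
  b <- max(bf, 1 / bf)
  if (b < 10^0.5) "barely worth mentioning"
  else if (b < 10) "substantial"
  else if (b < 10^1.5) "strong"
  else if (b < 100) "very strong"
  else "decisive"
}

#' Fit and compare the three jerk-preference models
#'
#' The model-comparison front end: computes the marginal likelihood of
#' Models A, B and C for a jerk-preference dataset under shared priors and
#' returns their Bayes-factor comparison.
#'
#' @param data A [fit_dataset].
#' @param priors A [pref_priors]; defaults to [pref_priors]`(data,
#'   transition_bounds)`.
#' @param transition_bounds Allowed transition-point interval (jerk axis)
#'   used when building default priors.
#' @param kinds Model kinds to compare; default all three.
#' @param n_draws,refine Passed to [marginal_likelihood()].
#' @param seed RNG seed.
#' @return A `model_comparison` with an extra `ml` element (the per-model
#'   [marginal_likelihood] objects, including posterior means).
#' @export
compare_pref_models <- function(data, priors = NULL,
                                transition_bounds = NULL,
                                kinds = c("A", "B", "C"),
                                n_draws = 1e5, refine = TRUE, seed = NULL) {
  stopifnot(inherits(data, "fit_dataset"))
  if (is.null(priors)) pr <- pref_priors(data, transition_bounds) else pr <- priors
  seeds <- derive_seeds(seed, length(kinds))
  ml <- lapply(seq_along(kinds), function(i) {
    marginal_likelihood(kinds[i], pr, data, n_draws = n_draws,
                        refine = refine, seed = seeds[i])
  })
  cmp <- bayes_factors(ml)
  cmp$ml <- stats::setNames(ml, kinds)
  cmp$priors <- pr
  cmp
}
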