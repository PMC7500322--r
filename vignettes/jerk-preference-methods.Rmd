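---
title: "Methods: jerk-graded kinematics and paired-comparison preference models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: jerk-graded kinematics and paired-comparison preference models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jerkpref)
```

`jerkpref` implements a complete desk-scale pipeline for studying how the
*smoothness* of an artificial agent's movement relates to the preference
observers express for it: synthesize a family of grasp trajectories whose
jerk is controlled by a noise amplitude, run (or simulate) a side-by-side
two-alternative forced-choice comparison game over those stimuli, estimate
a preference strength per stimulus with the Bradley–Terry model, and
compare competing parametric shapes of the jerk–preference relation by
Bayes factors.  This vignette is the package's account of the underlying
models, the tunable parameters, and the numerical and design choices.

## Kinematic model and smoothness statistic

A single-joint point-to-point movement from angle $x_i$ to $x_f$ (degrees)
in $d$ seconds is modelled by the minimum-jerk quintic

$$\theta(t) = x_i + (x_f - x_i)\left[10\left(\tfrac{t}{d}\right)^3
 - 15\left(\tfrac{t}{d}\right)^4 + 6\left(\tfrac{t}{d}\right)^5\right],$$

the unique polynomial minimizing integrated squared jerk under zero
endpoint velocity and acceleration.  The reference movement used throughout
is a prosthetic-hand two-digit grasp: MP-joint flexion from 161.4° to 96.9°
in 0.4 s, sampled at 120 Hz (the motion-capture rate).

Smoothness is summarized by the **average absolute jerk**,

$$\bar{J} = \frac{1}{T}\int \left|\dddot\theta(t)\right|\,dt ,$$

in deg/s³, computed on the sampling grid with finite differences: a
five-point central stencil for the third derivative in the interior and
second-order one-sided stencils at the segment edges.  For the minimum-jerk
quintic the statistic has the closed form
$40\,|x_f - x_i| / (\sqrt{3}\, d^3)$, which the sampled estimate approaches
as the rate grows; this closed form is the package's internal oracle.

```{r jerk}
mj <- minimum_jerk_trajectory(161.4, 96.9, 0.4, rate = 120)
minimum_jerk_avg_abs_jerk(161.4, 96.9, 0.4)  # analytic
average_absolute_jerk(mj)                    # sampled, unfiltered
```

### The measurement chain, and two defensible values

Recorded joint angles are low-pass filtered before differentiation
(fifth-order Butterworth, 10 Hz cutoff, applied forward and backward for
zero phase delay) and the statistic is taken over the movement segment
only.  `jerk_pipeline()` reproduces that chain for synthetic movements:
static holds are appended (0.8 s at each posture, giving the 2.0 s
animation cycle), the padded signal is filtered, and the metric is taken
over the motion window.  Movement segmentation can also be automated with
a velocity threshold (`detect_movement_bounds()`, onset/offset at 5% of
peak angular velocity by default), replacing manual marking.

```{r variants}
jerk_pipeline(mj)                # filtered chain
jerk_pipeline(mj, cutoff = NULL) # no filtering
```

For the reference grasp the analytic value is $0.233\times 10^5$ deg/s³
and the filtered chain yields $0.221\times 10^5$; the value reported for
this movement in the literature, $0.20\times 10^5$, sits slightly below
both.  Whether that figure used filtering, a different segment marking, or
unrounded movement parameters is not recoverable (an unrounded duration
near 0.42 s reproduces it exactly); the package therefore exposes
filtering as an explicit step and reports both variants rather than
silently reconciling them.

A note on the zero-phase filter: a naive forward–backward pass started
from a zero filter state produces large edge transients (even a constant
input is distorted).  `lowpass_zero_phase()` therefore pads the signal by
odd reflection and removes the leading value (the filter has unit DC gain)
before each pass, so constants pass through exactly and endpoints are
usable.

## Jerk-graded stimuli

Stimuli are built by adding **temporally smooth Gaussian noise** to the
minimum-jerk trajectory:

$$x(t) = x_{\text{minjerk}}(t) + a \cdot \mathrm{SD} \cdot n(t)\, w(t),$$

* $n(t)$ — a stationary unit-variance Gaussian field, realized as white
  noise convolved with a Gaussian kernel and renormalized.  Its temporal
  smoothness is parameterized by the FWHM of its autocorrelation
  (`fwhm`, seconds): the correlation at lag `fwhm/2` is 0.5 by
  construction.  Default 0.05 s.
* $w(t)$ — an endpoint taper
  $(1-e^{-t/\tau})(1-e^{-(d-t)/\tau})$, rescaled to a maximum of 1, which
  is exactly zero at both ends so every stimulus starts and ends on the
  reference postures regardless of the noise draw.  Default
  $\tau = d/20$.
* $\mathrm{SD}$ — the dimensionless noise amplitude of the stimulus grid,
  $\{0, 0.5, 1.0, \ldots, 4.0\}$ (nine conditions; $\mathrm{SD}=0$ *is*
  the minimum-jerk trajectory, bit-identically).
* $a$ — `amp_scale`, the calibration constant mapping one SD unit to
  degrees.  The physical unit of the noise is not fixed a priori;
  `calibrate_noise_units()` chooses $a$ by Monte-Carlo root-finding so
  that the *mean* realized jerk at $\mathrm{SD}=0.5$ equals a target —
  by default $0.50\times10^5$ deg/s³, the human jerk level that anchors
  the grid (so $\mathrm{SD}=0.5$ plays the role of "human-like
  roughness").  Calibration uses 200 common-random-number draws and is
  stored with every condition set.

```{r conditions, eval = FALSE}
cal <- calibrate_noise_units(mj, target_jerk_at_half = 0.5e5, seed = 101)
cs <- generate_condition_set(seed = 202, calibration = cal)
cs$conditions
```

Two consequences of this construction are worth knowing.  First, because
the measurement chain low-pass filters at 10 Hz, the *draw-to-draw*
variability of realized jerk is essentially independent of `fwhm` (the
filter sets the effective smoothness); with a single realization per
condition the realized jerks are typically *not* monotone in SD, even
though their expectation is.  A real experiment has the same property —
one realization per condition — so analyses downstream use the realized
jerk of each stimulus, not its nominal SD, as the abscissa.  Second,
endpoint preservation is exact (not approximate) for every amplitude and
seed, because the taper is exactly zero at the ends.

## The comparison game and its simulation

All ordered pairs of the $k=9$ conditions are shown side by side — each
unordered pair once in each left–right arrangement — in random order: 72
trials, with the observer choosing the more natural-looking animation.
`build_schedule()` constructs this balanced schedule; `tabulate_choices()`
accumulates choices into a win-count matrix $T$ with pair counts
$n_{ij} = T_{ij} + T_{ji}$.

Synthetic observers (`observer_spec()`) choose by the Bradley–Terry rule
$P(i \text{ over } j) = p_i/(p_i+p_j)$, with strengths given either
directly or through a latent preference curve $f$ over jerk via
$p_i = \exp\{\beta f(x_i)\}$.  The exponential link guarantees positive
strengths for any curve, but it is worth noting that it distorts curve
*shape*: the expected Bradley–Terry profile is $e^{\beta f}$ normalized,
which is convex in $f$, so choices generated from a linear curve do not
produce exactly linear preference data.  When a test requires the
preference profile itself to equal a model curve, strengths are passed
directly (`strengths = f(x)`), which the choice rule permits whenever the
curve is positive.  Presentation side never enters the probability.

The pipeline's default observers use the exponential link with
$\beta = 2$ over unit-range curves, so the strongest-to-weakest strength
ratio is $e^2 \approx 7$ — matching the roughly five-to-one spread seen
between the most and least preferred stimuli in group-level preference
data, and keeping every condition off the zero-win boundary at realistic
subject counts.

## Bradley–Terry estimation

`bt_fit()` computes the maximum-likelihood strengths on the unit simplex,
solving the stationarity conditions

$$\frac{T_i}{p_i} = \sum_{j \neq i} \frac{n_{ij}}{p_i + p_j},
\qquad \sum_i p_i = 1$$

by the Zermelo/Ford minorization iteration
$p_i \leftarrow T_i \big/ \sum_{j\ne i} n_{ij}/(p_i+p_j)$ with
renormalization, started from the uniform vector.  The iteration increases
the likelihood monotonically; convergence is declared when the largest
change in $p$ falls below `tol` (default 1e-10, within machine precision
of the fixed point for these problem sizes).  Two degeneracies are
handled explicitly: a disconnected comparison graph is an error (strengths
are not jointly identified), and a condition with zero wins — for which
the MLE sits on the simplex boundary — triggers a flagged fall-back that
adds 0.5 pseudo-counts to every compared pair.  Subjects are pooled into
one table before fitting, matching group-level analysis; per-subject
tables remain available for diagnostics.

```{r bt}
fit <- bt_fit(matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE))
coef(fit)
pairwise_preference(fit, 1, 2)
```

## Piecewise preference models and Bayesian comparison

Three shapes for the relation between average absolute jerk $x$ and
Bradley–Terry preference are compared:

$$\begin{aligned}
\text{Model A (linear):}\quad & f(x) = a_0 + a_1 x\\
\text{Model B (flattened):}\quad & f(x) = b_0 + b_1 \min(x, b_2)\\
\text{Model C (reversed):}\quad & f(x) = c_0 + c_1 x \;\; (x < c_2),
\qquad c_0 - c_1 x + 2 c_1 c_2 \;\; (x \ge c_2)
\end{aligned}$$

B and C are continuous at their transition points by construction; C's
slope flips sign there, giving a peaked (or dipped) profile.  The
transition points are restricted to the low-jerk region — the jerk values
of conditions with $\mathrm{SD} < 1.5$ — and the fit uses only conditions
with $\mathrm{SD} < 3.0$ (six of nine), both restrictions entering through
`fit_dataset()` and the prior truncation.

The observation model (not stated in the source analysis, so a package
choice) is Gaussian: $y_i \sim N(f(x_i), \sigma)$ over included points,
with a half-normal prior on $\sigma$.  Priors are deliberately weak and
scale with the data: intercepts $N(\bar y, 10\,s_y)$, slopes
$N(0, 10\,s_y/s_x)$, transitions truncated-normal over the allowed
interval, $\sigma \sim \text{half-}N(10\,s_y)$ (`pref_priors()`, `scale`
configurable and logged per run).

**Posterior sampling** (`sample_posterior()`) uses componentwise adaptive
random-walk Metropolis with split-$\hat R$ and autocorrelation-based
effective sample sizes; $\hat R > 1.1$ raises a warning rather than
failing silently.  Defaults (20 000 kept iterations, 2 000 burn-in,
thinning 6, 2 chains) are deliberate desk-scale settings; the reference
analysis ran $10^6$ iterations with the same burn-in and thinning, and
those values can be passed directly for a faithful run.

**Marginal likelihoods** are estimated by direct Monte-Carlo integration
over the prior — all models have at most four free parameters — refined by
defensive importance sampling: a second pass draws from an equal mixture
of the prior and an independence proposal moment-matched to the
likelihood-weighted first-pass draws (log-normal component for $\sigma$,
truncated normal for the transition).  The estimator is unbiased on the
evidence scale and reports a Monte-Carlo standard error; on a conjugate
linear-Gaussian test problem it matches the closed-form evidence within
1% at the default $10^5$ draws.  Bayes factors
$\mathrm{BF}_{ij} = \exp(\log \mathrm{ML}_i - \log \mathrm{ML}_j)$ then
satisfy reciprocity and transitivity exactly by construction, and are
labelled on the conventional half-decade evidence scale (`"barely worth
mentioning"` below $10^{1/2}$, then `"substantial"`, `"strong"`,
`"very strong"`, `"decisive"` above 100), applied to
$\max(\mathrm{BF}, 1/\mathrm{BF})$.  Note that some published uses of
these labels do not match the standard bands (e.g., calling 8.3 "very
strong"); the package implements the standard bands and leaves the
discrepancy to the reader.

## What the synthetic data do and do not show

The generator emulates: minimum-jerk reference kinematics at 120 Hz;
endpoint-constrained smooth noise with calibrated amplitude; the 72-trial
balanced design; Bradley–Terry choice behaviour with optional latent
preference curves.  It does **not** emulate: left–right side bias,
response times, learning or fatigue across trials, per-subject
heterogeneity in the preference curve (subjects differ only through
independent choice randomness), marker-swap artifacts, or the visual
appearance of the stimuli.  Passing model-recovery tests therefore shows
that the estimation and comparison machinery is correct and well
calibrated at realistic sizes — not that real observers behave like any
of the three curves.

Model-recovery is verified at the study's scale: six conditions inside the
analysis range with jerk-like abscissae, preference values on the
Bradley–Terry scale (~0.1), observation noise 0.005, 20 seeded replicates
per generating shape; the generating model attains the highest evidence in
at least 80% of replicates for each shape.

## Numerical choices and degenerate inputs

* Third derivative: five-point central stencil, one-sided second-order
  stencils at edges; four-sample segments fall back to the single
  third-difference.
* Trajectories are validated to be uniformly sampled within 1e-9 s and at
  least 4 samples long; `d * rate` must be a whole number of intervals so
  the closed interval $[0, d]$ includes both endpoints exactly.
* Coincident markers (angle undefined) raise an error naming the first
  offending frame; angle computation clamps cosines to $[-1, 1]$.
* `sd = 0` short-circuits synthesis (bit-identical input); a calibration
  target equal to the baseline returns `amp_scale = 0`; an unattainable
  target is an error with diagnostics.
* All randomness flows through explicit seeds; child seeds are derived
  from a master seed, and library calls never disturb the caller's RNG
  state.
* Monte-Carlo sizes used by the test suite (chosen once): 200 calibration
  draws, 200 draws per grid level for monotonicity, ~1e4 pooled
  comparisons for Bradley–Terry recovery, 3e4 evidence draws inside
  recovery loops and 1e5 by default elsewhere.

## Known limitations

Single degree of freedom only (one joint angle); no ties or side-bias
terms in the choice model; no hierarchical per-subject preference model;
the marginal-likelihood method relies on low parameter dimension and
would need replacing (bridge or nested sampling) for richer models; the
numerical Bayes factors of the original human experiments are not
reproducible because the underlying choice data are unpublished — all
fitting beyond the printed pipeline constants runs on synthetic data by
design.
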