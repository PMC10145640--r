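---
title: "Estimating whole attachment times from prevalent-cohort drop-off data"
author: "tickaft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating whole attachment times from prevalent-cohort drop-off data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tickaft)
```

# The sampling model

A captured host carries a set of ticks that are all mid-feed: a prevalent
cohort. Write `T` for the whole attachment time of a tick (days from
landing to drop-off), `B` for the backward recurrence time (landing to host
capture) and `V = T - B` for the forward recurrence time (capture to
drop-off). Only `V` is observable, and only in one-day bins: a tick that
drops off during day `d` after capture is recorded at the bin midpoint
`d - 0.5` days.

Three assumptions connect the law of `V` to the law of `T`:

1. **Weibull whole times.** `T ~ Weibull(k, λ)`, density
   `f(t) = (k/λ)(t/λ)^{k-1} e^{-(t/λ)^k}`, a standard flexible family for
   durations.
2. **Length-biased inclusion.** The chance that a tick is on the host at
   capture is proportional to `T`, so the sampled whole time `T*` has
   density `t f(t)/E[T]`.
3. **Uniform interruption.** Capture falls uniformly inside the attachment
   spell, so `V = U·T*` with `U ~ Uniform(0,1)` independent of `T*`.

Together these give `V` the equilibrium (renewal-theory) density

$$ f_V(v) \;=\; \frac{S_T(v)}{E[T]} \;=\;
   \frac{e^{-(v/\lambda)^k}}{\lambda\,\Gamma(1+1/k)}, $$

which is a generalised gamma law, monotone non-increasing in `v` for every
parameter value. Its distribution function reduces to a regularised
incomplete gamma, $F_V(v) = P\{\Gamma(1/k) \le (v/\lambda)^k\}$, which the
package uses for interval-censored likelihoods and residuals. The package
treats this equilibrium form as the definition of the observed-time model;
it is the unique law consistent with assumptions 1–3.

Two consequences carry the whole analysis:

* the same scale parameter (and hence the same regression coefficients)
  governs `T` and `V`, so a regression fitted to observed times transfers
  to whole times; and
* the ratio of means depends on the shape alone,
  $E[T]/E[V] = 2\Gamma(1+1/k)^2/\Gamma(1+2/k)$, which is 1 at `k = 1`
  (memoryless: the forward law of an exponential is the exponential),
  increases strictly in `k`, and tends to 2 as `T` degenerates to a point
  mass (`V` then uniform on `(0, λ)`). `mean_ratio()` and its delta-method
  interval `mean_ratio_ci()` implement this; the derivative
  $R'(k) = R(k)\,(2/k^2)\,[\psi(1+2/k)-\psi(1+1/k)]$ is analytic
  (`mean_ratio_deriv()`), and tests verify it against central differences.

All gamma-function arithmetic is done in log space (`lgamma`), and all
densities are evaluated as log densities internally, so shapes up to the
hundreds and `v/λ ≫ 1` do not overflow.

# The regression model and its estimation

`fraft()` fits the accelerated failure time model
$\log \lambda_i = x_i'\beta$ with a single shape `k` shared by all
observations, by maximum likelihood on the forward-recurrence density.
Covariates in the motivating design are tick stage (larva, nymph, female,
male; larva is the reference), season (spring, summer, autumn; spring
reference) and their interaction; the reported quantities (per-cell means
and their ratios) do not depend on the coding.

**Time conventions.** The default (`"midpoint"`) treats the recorded bin
midpoints 0.5, 1.5, … as exact observations of `V` — matching the field
convention of feeding half-integer days to a parametric fitter. The
`"interval"` option instead uses the exact bin probability
$F_V(d) - F_V(d-1)$. Whether the original analysis treated the midpoints
as exact is not documented; both are provided, and on day-scale data with
scales of three days or more the two shape estimates agree within a few
per cent (tested). The interval likelihood clamps bin probabilities at
`1e-300` before taking logs so that extreme shapes explored during
profiling cannot produce `-Inf`.

**Profile likelihood.** Standard AFT software requires the shape of this
observed-time family to be fixed in advance, so the package profiles it
out: for fixed `log k` the coefficients are maximised by BFGS with the
analytic gradient $\sum_i w_i (k u_i - 1) x_i$, $u_i = (v_i/\lambda_i)^k$;
the outer search over `log k` is Brent's method on `log [0.3, 30]` with
tolerance `1e-8`, followed by a second localised pass (±0.02 on the log
scale) that removes the small path dependence introduced by warm-starting
the inner optimiser. The profile log-likelihood is unimodal on all tested
instances, and fits started from different outer brackets agree to
`1e-6` in the shape. The shape standard error is taken from the numerical
curvature of the profile log-likelihood at the optimum (step `1e-3` on the
log scale).

**Cluster-robust covariance.** Ticks from one host share exposures, so the
covariance of $(\beta, \log k)$ is the sandwich
$B^{-1} \left(\sum_c s_c s_c'\right) B^{-1}$ with `B` the observed
information at the optimum and $s_c$ the cluster-summed per-observation
scores (computed by central differences, which keeps the midpoint and
interval conventions on one code path). Point estimates are invariant to
the cluster labels — only the covariance changes (tested by permuting
labels). Without a cluster argument, e.g. when fitting the published
day-binned aggregate where per-host identities are unpublished, the
model-based inverse information is used and the fit is flagged
`robust = FALSE`.

**Back-transformation.** `predict(fit, type = "whole_mean")` and
`group_means()` return $\hat E[V]_g = \lambda_g \Gamma(1+2/k)/(2\Gamma(1+1/k))$
and $\hat E[T]_g = R(k)\,\hat E[V]_g$ per covariate cell with delta-method
intervals on the log scale; the `E[T]/E[V]` column is constant across
cells because the shape is common.

**Sensitivity analysis.** Fewer ticks drop off on the first day after
capture than the monotone density predicts (a capture-stress artefact).
`merge_day12()` assigns the common observed time of 1 day to everything
recorded on days 1–2; refitting the bundled day-bin table this way moves
every per-stage whole-time mean by less than 3 per cent, so the headline
estimates are not driven by the day-1 deficit. The deficit itself is
tested by `day12_test()` (below). Day-1 records are retained in the main
fit; the sensitivity refit is the mitigation.

# The abundance model

`abundance_fit()` is the marginal Poisson model of per-host tick counts by
stage × season: a log-linear saturated fit with working independence,
whose point estimates are therefore exactly the cell sample means (cell
total / hosts in season) — which is why the modelled and observed columns
of its report table coincide. Correlation between the counts of different
stages on one host enters through the host-clustered sandwich covariance
(`sandwich::vcovCL`); an exchangeable working correlation is available and
provably leaves the saturated point estimates unchanged. When only printed
cell totals are available the counts are spread over pseudo-hosts — point
estimates are exact, but the fit is flagged because the covariance then
reflects a fabricated allocation. All-zero cells are reported at the
boundary (mean 0) with the exact Poisson upper bound
$-\log(\alpha/2)/n_{\text{hosts}}$ and flagged.

`cell_contrasts()` compares modelled means between stages within season
and between seasons within stage on any fit exposing log cell means
(both the abundance fit and the AFT fit do; for the AFT, differences of
log scales equal differences of log whole-time means because the shape is
common). The multiplicity adjustment is the single-step max-|z| method:
the joint normal law of the standardised contrasts is sampled with a fixed
seed (20230329, `1e5` draws), each adjusted p-value is the tail
probability of the largest absolute deviate, and the same distribution
supplies the critical value for simultaneous intervals. Monte-Carlo noise
can nominally push an adjusted p below the raw p; the implementation
enforces `p_adjusted >= p_raw`. Holm is available as a deterministic
fallback, with per-comparison intervals. The 5% level is used throughout.

# The day-1 deficit test

`day12_counts()` tabulates per host and stage the ticks recorded on days 1
and 2; `day12_test()` fits a negative binomial (NB2, variance
$\mu + \mu^2/\theta$) mixed model with fixed effects
`day + stage + day:stage` and a random host intercept, and reports the
day-2/day-1 rate ratio with a Wald test per stage (or with larvae and
nymphs pooled as subadults — both groupings are supported because the
original report is ambiguous about the pooling). The default fitter is
glmmTMB's Laplace approximation; an adaptive Gauss–Hermite fitter (15
nodes by default, nodes by Golub–Welsch) is implemented in the package for
the one-dimensional random intercept, agrees with Laplace within 2% on
well-separated data (tested), and allows fixing `θ` or the random-effect
variance — driving both to their limits reproduces a plain Poisson GLM to
`1e-4`, which is the main correctness anchor.

# The synthetic cohort generator

`simulate_cohort()` generates data with exactly the structure the analysis
assumes, so that every estimator can be tested against known truth:

* hosts on a weekly capture schedule (default: 57 hosts over 27 weeks;
  18 spring, 27 summer, 12 autumn);
* per-host, per-cell tick counts Poisson with mean
  `abundance_mean × frailty`, the frailty log-normal with sd 0.65 on the
  log scale — chosen once from the observed coefficient of variation
  (≈0.74) of the largest abundance cells under a Poisson-lognormal model,
  since the within-host dispersion was never published;
* whole times from the length-biased Weibull law with one shared shape
  (default 4.5) and per-cell scales back-solved so that the model's
  observed-time means equal the published per-cell observed means — these
  defaults are a convenience calibration, not ground truth;
* capture position uniform over the spell; drop-off recorded at day-bin
  midpoints `ceil(V) - 0.5`.

Two samplers are provided and tested against each other in distribution:
the default simulates the mechanism (attachment onsets homogeneous-Poisson
on a window ending at capture, window at the 99.99th percentile of the
whole-time law, ticks still attached at capture retained), and the direct
sampler uses the exact Gamma representation of the length-biased Weibull,
$T^* = \lambda G^{1/k}$ with $G \sim \Gamma(1+1/k)$. Records carry the
latent whole, backward and forward times for recovery tests.

Design choices worth noting:

* **Frailty acts on abundance only** by default, matching the marginal
  estimand (the original model handles within-host correlation through
  robust errors, not shared duration effects). Because that leaves
  durations independent given covariates, an optional
  `duration_frailty_sd` (log-normal multiplier on the Weibull scale per
  host, default 0) exists to induce genuine duration clustering — used to
  demonstrate that the sandwich exceeds the naive covariance when
  clustering is real.
* **Day-1 suppression is off by default** (`day1_suppression_prob = 0`):
  the clean generative model is the reference; the capture-stress artefact
  is an explicit perturbation (`apply_day1_suppression()`, default sparing
  males) used in power studies of the day-1/2 test.
* ***I. hexagonus*** ticks are generated as inert labels (0.65% by
  default, nymph-stage durations) and excluded from model fits, as in the
  source data.
* **Status labels** (engorged / dead / imperfect) are drawn per stage with
  the published proportions; they are descriptive only.

What the generator does **not** emulate: recaptures, questing dynamics,
weather forcing, seasonal drift within a season cell, or any dependence of
attachment duration on host covariates. Passing recovery tests therefore
show that the estimators invert the sampling mechanism they assume; they
do not validate that mechanism against real field data.

# Numerical choices and problem sizes

* Outer shape search on `log [0.3, 30]`, Brent tolerance `1e-8`, with a
  localised polish pass; inner BFGS relative tolerance `1e-12`.
* Per-observation scores by central differences (`h = 1e-6 (1+|θ|)`);
  observed information by `optimHess`.
* Interval-censored bin probabilities floored at `1e-300`; the gradient
  term at a zero lower bin edge is set to its analytic limit 0.
* Degenerate inputs fail loudly: all-equal observed times (shape not
  identifiable), non-positive times, unknown factor levels, empty seasons.
* The test suite sizes its simulations to run on a laptop in minutes:
  calibration checks use 200–500 replicates at reduced cohort sizes
  (e.g. single-cell cohorts of a few hundred ticks for coverage, 57-host
  count tables for the mixed-model calibration), and the full-size
  parameter-recovery fit uses one seeded cohort of ≈4700 ticks. These
  sizes are the package's own trade-off between Monte-Carlo error and run
  time.

# Known limitations

* Only the Weibull whole-time family is implemented; the closed-form
  forward law, the Gamma-transform sampler and the shape-only mean ratio
  are all Weibull-specific. Other families (log-normal, gamma) would need
  their own equilibrium forms.
* The bundled published tables support only a stage-resolved attachment
  fit (the season-resolved per-tick raw data were never published), so
  reproductions of the whole-time means are stage-pooled; the per-cell
  published means are carried for reference, including the source tables'
  internal inconsistencies, which are preserved as printed.
* Wald-type intervals on log cell means undercover at very small counts
  (familywise coverage ≈92–93% at a handful of ticks per cell, returning
  to ≈95% at study-like burdens); a small-count analysis should prefer
  likelihood-ratio or exact intervals, which are not implemented.
* The day-1 deficit model treats suppression as a shift from day 1 to
  day 2 only; longer displacement is not modelled.
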