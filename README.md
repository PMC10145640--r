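# tickaft

Length-biased attachment-time and infestation analysis for tick drop-off
cohorts.

## The problem

When engorging ticks are collected from freshly captured hosts (here:
*Ixodes ricinus* on northern white-breasted hedgehogs sampled weekly in an
urban park), the ticks on each host form a **prevalent cohort**: every tick
is observed mid-feed, its attachment began at an unknown time, and only the
time from host capture to drop-off — the **forward recurrence time** `V`,
recorded in one-day bins at midpoints 0.5, 1.5, … days — is seen. Two
biases separate `V` from the quantity of interest, the **whole attachment
time** `T` (landing to drop-off):

* **length-biased sampling** — a tick that stays attached longer is more
  likely to be on the host at capture, so sampled whole times have density
  `t f(t) / E[T]`;
* **interruption** — capture lands uniformly inside the attachment spell,
  so only the remaining part of the spell is observed.

Under these two assumptions, if `T ~ Weibull(k, λ)` then `V` has the
equilibrium (renewal) density

```
f_V(v) = S_T(v) / E[T] = exp(-(v/λ)^k) / (λ Γ(1 + 1/k)),
```

a monotone non-increasing generalised gamma law, and the ratio of mean
whole to mean observed time depends on the shape alone:

```
E[T] / E[V] = 2 Γ(1 + 1/k)² / Γ(1 + 2/k)  ∈ (0, 2).
```

`tickaft` fits an accelerated failure time (AFT) regression on this
forward-recurrence likelihood — `log λ_i = x_i'β` with a common shape `k`
profiled out, and host-clustered sandwich covariance — and back-transforms
observed-scale means to whole-scale means through the shape-only ratio. It
is written for parasitologists and biostatisticians analysing drop-off data
from captured hosts, and for methodologists studying length-biased duration
models.

Around the core model the package provides:

* a saturated marginal Poisson (GEE-style) model of per-host tick abundance
  by stage × season with host-clustered standard errors
  (`abundance_fit()`, `abundance_table()`);
* single-step max-|z| multiplicity-adjusted ratio contrasts between stages
  within season and seasons within stage (`cell_contrasts()`);
* a negative binomial mixed model testing whether fewer ticks drop off on
  day 1 than day 2 after capture (`day12_counts()`, `day12_test()`), with
  both a Laplace (glmmTMB) and an adaptive Gauss–Hermite fitter;
* descriptive parasitology (`cohort_summary()`, `totals_summary()`,
  `weekly_series()`, `count_peaks()`);
* a seeded synthetic cohort generator with the exact sampling structure the
  model assumes, carrying latent truth for recovery studies
  (`sim_config()`, `simulate_cohort()`);
* the printed summary tables of the motivating field study, bundled as CSV
  (`study_fixtures()`), and a one-call reproduction of the whole analysis
  (`reproduce_study()`).

## Worked example

Fit the forward-recurrence AFT to the bundled day-binned drop-off counts
(stage as covariate, day-bin midpoints as observed times):

```r
library(tickaft)
fx <- study_fixtures()
bins <- fx$daybins
bins$observed_day <- bins$day - 0.5
fit <- fraft(observed_day ~ stage, data = bins, weights = count)
summary(fit)
#> Forward-recurrence Weibull AFT
#> 41 records (total weight 4691), convention 'midpoint'
#>             Estimate Std. Error z value Pr(>|z|)
#> (Intercept)  1.32941    0.01261  105.40   <2e-16 ***
#> stagenymph   0.22125    0.01555   14.23   <2e-16 ***
#> stagefemale  0.91767    0.02799   32.78   <2e-16 ***
#> stagemale    0.70862    0.05661   12.52   <2e-16 ***
#>
#> Shape: 4.147 (se 0.113)   log-likelihood: -7887.82
#> Whole/observed mean ratio: 1.863 (95% CI 1.850-1.875)

print(group_means(fit), digits = 3)
#>    stage observed_mean observed_lower observed_upper whole_mean whole_lower whole_upper mean_ratio
#> 1   male          3.74           3.36           4.17       6.97        6.25        7.78       1.86
#> 2 female          4.61           4.39           4.85       8.59        8.16        9.05       1.86
#> 3  nymph          2.30           2.25           2.35       4.28        4.18        4.38       1.86
#> 4  larva          1.84           1.80           1.89       3.43        3.34        3.52       1.86
```

Reading the output: the fitted common shape is 4.15, so whole attachment
times are estimated to be 1.86 times the observed (capture-to-drop-off)
times — identically in every group, because the ratio depends only on the
shape. Larvae stay attached about 3.4 days in total, nymphs 4.3, males 7.0
and females 8.6, even though the observed times are roughly half that.
Coefficients are log-scale effects on the Weibull scale λ relative to
larvae.

The whole published analysis — descriptives, the abundance model with
post hoc ratio contrasts, the AFT fit, and the day-1/2 merging sensitivity
refit — runs with:

```r
rep <- reproduce_study()
print(rep)
```

A thin command-line front end over the same functions is installed at
`system.file("cli", "tickaft.R", package = "tickaft")` with subcommands
`simulate`, `fit-attachment`, `abundance`, `dropoff-test`, `describe`,
`sensitivity` and `reproduce-study`, all seeded and writing JSON/CSV
reports.

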