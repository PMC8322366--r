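---
title: "Modelling sensor non-collection in duty-cycled smartphone studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sensor non-collection in duty-cycled smartphone studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dutymiss)
```

## The problem

Smartphone digital-phenotyping platforms sample high-frequency sensors
(accelerometer, GPS) on an investigator-configured duty cycle: the
sensor records for `on_cycle_s` seconds, sleeps for `off_cycle_s`
seconds, and repeats. The schedule makes part of the missingness
*by design* and, crucially, makes the expected data volume known in
advance: a 1-minute-on / 9-minutes-off GPS schedule yields 10% coverage,
2.4 h of data and `floor(86400 / 600) = 144` collection attempts per
24-h day. What the schedule does not control is *sensor non-collection*:
attempts that produce no data because the phone was off, the sensor was
disabled, or the operating system suppressed collection. dutymiss
quantifies that second kind of missingness from nothing but measurement
timestamps, and models how it varies over time, across people and
across studies.

## From raw timestamps to a participant-day panel

Raw timestamps are segmented into **measurement groupings**: maximal
runs of measurements separated from the next run by a gap of at least
half the off-cycle (`segment_events()`). The "at least" is a firm
tie-break — a gap of exactly `off_cycle_s / 2` starts a new grouping.
Each grouping is assigned to the calendar day containing its *start*
time, so a grouping straddling midnight is never counted twice. Days are
cut at local midnight in a configurable timezone (UTC by default; the
choice only shifts which attempts land on which day, not their number).

For each participant-day the panel (`build_daily_panel()`) records the
number of missing groupings

y = max(0, E - observed groupings),

where the offset `E = floor(86400 / (on + off))` is the design-expected
count, with partial trailing cycles ignored (a conservative, fixed
choice). Days where clock drift or OS bursts produce *more* groupings
than expected are clipped at zero missing and flagged in the `overrun`
column. Follow-up spans each participant's first to last observed day
inclusive; interior days with no data at all contribute `y = E`.
Partial first/last days are retained as full days by default
(`drop_partial_days = TRUE` excludes them — the right choice when
enrollment times are mid-day and bias matters more than sample size).

## The model

Daily missing-grouping counts are overdispersed (a phone that is off
all evening kills whole blocks of attempts), so the panel is modelled
with a hierarchical negative-binomial regression. For participant *i*
in study *j*:

$$y_{ij} \sim \mathrm{NegBin}(\mu_{ij}, \omega), \qquad
\log \mu_{ij} = \log E_j + \alpha_0 + \beta_1 X_{1ij} + \dots +
\beta_p X_{pij} + \gamma_{0ij} + \delta_{0j},$$

$$\gamma_{0ij} \sim \mathrm{N}(0, \sigma_\gamma^2), \qquad
\delta_{0j} \sim \mathrm{N}(0, \sigma_\delta^2),$$

with `Var(y) = mu + mu^2 / omega` (inverse overdispersion; the Poisson
limit is `omega -> Inf`). `exp(alpha0)` is the expected *proportion* of
attempts missed at week 0 by a reference-group participant;
`exp(beta)` are rate ratios. Fixed-effect covariates: time in study in
**weeks** since each participant's own first day (uncentered, so the
intercept is the beginning-of-study rate; weekly rate ratios are the
convention for reporting this coefficient, and `(exp(beta) - 1) * 100`
is the percent change per week), OS (iOS vs Android reference), gender
(male vs female reference), education (4-year degree or higher vs less),
race/ethnicity (indicator contrasts against non-Hispanic White) and age
in decades. Participants missing any modelled covariate are excluded
entirely (complete-case analysis, `complete_case_filter()`); no
imputation is attempted.

### Priors

Slopes get improper flat priors. The intercept gets a diffuse
Student-t(3, 6.7, 2.5); 6.7 is a conventional response-derived centering
constant, exposed as `intercept_prior_loc` and recomputed from the panel
as `median(log(y + 0.5))` when set to `"auto"`. Random-effect SDs get
half-Student-t(3, 0, 2.5). No established convention pins the shape
prior; dutymiss uses the conventional diffuse Gamma(0.01, 0.01) on
`omega`, configurable via `omega_prior_shape` / `omega_prior_rate`.
With thousands of participant-days, all results are likelihood-dominated
except `sigma_delta`, whose posterior with ~6 studies leans visibly on
its half-t prior — exactly as intended for a weakly identified scale.

### Sampling and convergence

The joint posterior is sampled by the package's own No-U-Turn sampler
(R driver, compiled log-posterior and gradient). The two random-effect
levels get different parameterizations, chosen by how strongly the data
identify them: participant intercepts, with tens of observations each,
are sampled **centered** (the centered geometry is well conditioned
when groups are data-dominated, and it decouples each intercept from
`sigma_gamma`); study intercepts, few in number with a weakly
identified scale, are sampled **non-centered** to avoid the
classic funnel. Both choices are posterior-invariant. Warmup uses
dual-averaging step-size adaptation (target acceptance 0.8) around
expanding diagonal mass-matrix windows, then a final step-size-only
phase. Initialization is jittered around a moment-matched intercept;
a non-finite starting density triggers re-initialization (up to
`init_attempts`).

Convergence is judged exactly as modern practice dictates:
rank-normalized split R-hat *and* its folded variant (scale
sensitivity) must both be at most 1.01 for every parameter, and bulk
and tail effective sample sizes must reach 100 per chain. The
implementations are checked in the test suite against an independent
reference implementation of the same recipe to 1e-6. `fit_noncollection()`
never errors on non-convergence — it flags the fit, and the report
builders refuse to run without an explicit override. Constant chains
make R-hat undefined; it is reported as `Inf` with a warning.

### Model comparison

`waic()` and `loo_psis()` are computed on the deviance scale from the
per-observation log-likelihood matrix. PSIS-LOO smooths each
observation's largest importance ratios with a generalized-Pareto fit
(Zhang–Stephens posterior-mean estimator with the standard weak shape
prior); observations with Pareto k > 0.7 are reported with a warning
but are not fatal. Bayes R-squared uses the negative-binomial
response-scale residual variance per draw,

$$R^2_s = \frac{\mathrm{var}_n(\mu_s)}{\mathrm{var}_n(\mu_s) +
\mathrm{mean}_n(\mu_s + \mu_s^2/\omega_s)},$$

with the population (1/n) variance; the posterior of `R2` is summarized
by its median and central 95% interval.

### Summaries

Rate ratios are summaries of exponentiated draws, never exponentiated
summaries. For the median and quantiles the two coincide (monotone
transform); because they differ for means, `tidy()` reports both the
median (`estimate`) and the mean (`estimate_mean`) of `exp(beta)`,
clearly labelled. The `std.error` column is the posterior SD of `beta`
on the log scale.

## The synthetic-data generator

Real event streams from the studies this model was developed on cannot
be redistributed, so the package validates itself end-to-end on
synthetic data with full ground truth (`simulate_study()`).

* **Cohort**: covariates drawn independently per participant at
  configurable marginals whose defaults mirror the published six-study
  cohort: 23% iOS, 66% female, 67% high-school education, 55%
  non-Hispanic White, age 25.4 (SD 10.8) years, with ~1–4%
  masked-as-missing reports for gender/education/race (the generative
  model keeps the unmasked value; the reported table gets `NA`, which
  exercises the complete-case filter).
* **Panel**: `delta` per study, `gamma` per participant, `y ~ NB(mu,
  omega)` per day. Draws exceeding the ceiling `E` are **clipped to
  E** and the clip rate is recorded in the ground truth and pipeline
  manifest. Bounded counts cannot literally be negative binomial — the
  ceiling effect is a real feature of this design — and clipping makes
  the resulting attenuation measurable rather than hidden: at the
  published GPS parameters roughly 8–9% of person-days clip, which
  biases recovered `sigma_gamma` and the intercept toward zero by an
  amount comparable to one posterior SD at desk scale.
* **Streams**: for each day, `y` of the `E` on-cycles are dropped
  uniformly at random (drops are exchangeable within a day; no battery
  or OS mechanism is simulated) and events are emitted at 1 Hz inside
  retained cycles — any within-cycle rate with spacing below half the
  off-cycle gives identical segmentations.
* **Determinism**: every unit (participant, study, day) draws from a
  sub-seed derived from the master seed, so enlarging the cohort never
  perturbs existing participants' draws and all outputs are
  reproducible bit-for-bit.

What the generator does *not* emulate: temporally correlated drops
(battery depletion arcs), participant attrition, covariate
correlations, study-specific schedules within one run. Passing
recovery tests therefore demonstrates correctness of the estimation
machinery under the model's own assumptions plus the ceiling effect —
not robustness to every failure mode of real deployments.

A fundamental observability limit checked by the round-trip tests:
days of total non-collection at the very start or end of follow-up
leave no events, so a panel rebuilt from streams cannot know they
existed. `trim_unobservable_days()` restricts simulated truth to each
participant's observable span before comparison; interior all-missing
days are recovered exactly.

## Problem sizes

The test suite favors many small, seeded checks: segmentation is
verified against a brute-force oracle on 200 random streams of up to
10,000 events; stream/panel round trips on 50 random configurations;
the replicate recovery study runs 10 replicates of 3 studies x 12
participants x 40 days with 4 chains of 300+300 iterations — large
enough that all three targeted coefficients (intercept, weekly trend,
iOS) are comfortably identified, small enough to keep the full suite
in minutes. The acceptance script runs the full desk-scale recovery
(6 studies x 30 participants x 90 days, 4 chains of 400 warmup + 900
sampling iterations) for the accelerometer and GPS parameter sets.

## Known limitations

* A single sensor schedule per run; per-study schedules are handled by
  running the pipeline per study/sensor with its own design config.
* The ceiling effect is simulated and measured but not corrected; a
  bounded-count likelihood is deliberately out of scope.
* With very few studies, `sigma_delta` is prior-sensitive; the
  no-study-random-effect sensitivity refit is one `model_spec()` toggle
  away.
* The sampler is single-threaded; chains run sequentially.
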