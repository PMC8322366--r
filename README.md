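# dutymiss

Quantifying **sensor non-collection** in duty-cycled smartphone
digital-phenotyping studies.

Platforms like Beiwe sample phone sensors on an investigator-chosen
duty cycle — e.g. GPS on for 1 minute, off for 9 — so the expected
number of daily collection attempts ("measurement groupings") is known
by design: `floor(86400 / 600) = 144` per day, 10% coverage, 2.4 h of
data per 24 h. Attempts that return no data (phone off, sensor
disabled, OS suppression) are *sensor non-collection*, the missingness
that actually threatens downstream analyses. dutymiss turns raw
measurement timestamps into that quantity and models it:

1. **Segment** timestamps into measurement groupings: maximal runs
   separated by gaps of at least half the off-cycle
   (`segment_events()`).
2. **Panel**: one row per participant-day with `y = max(0, E -
   observed groupings)` and the design offset `E`
   (`build_daily_panel()`).
3. **Model**: Bayesian hierarchical negative-binomial regression

   ```
   y_ij ~ NegBin(mu_ij, omega)
   log(mu_ij) = log(E_j) + alpha0 + X beta + gamma_ij + delta_j
   gamma_ij ~ N(0, sigma_gamma^2)   # participant intercepts
   delta_j  ~ N(0, sigma_delta^2)   # study intercepts
   ```

   fit by the package's own No-U-Turn sampler (compiled gradient,
   centered participant / non-centered study intercepts), with
   rank-normalized split R-hat +
   folded R-hat and bulk/tail ESS convergence gates, WAIC, PSIS-LOO
   and Bayesian R-squared (`fit_noncollection()`).
4. **Simulate**: a synthetic cohort / panel / raw-event-stream
   generator with complete ground truth, used to validate every stage
   end-to-end since real streams cannot be redistributed
   (`simulate_study()`, `run_recovery()`).

## Worked example

Simulate a small cohort from known parameters and recover them:

```r
library(dutymiss)

cfg <- sim_config(n_studies = 3, participants_per_study = 8,
                  days_per_participant = 20, seed = 301)
truth <- true_params(alpha0 = log(0.3),
                     beta = c(week = log(1.02), os_ios = log(0.7)),
                     sigma_gamma = 0.6, sigma_delta = 0.2, omega = 1)
sim <- simulate_study(cfg, truth)

fit <- fit_noncollection(sim$panel,
                         model_spec(terms = c("week", "os_ios")),
                         mcmc_spec(chains = 4, warmup = 250, iter = 250,
                                   seed = 99))
tidy(fit)
#> # A tibble: 3 x 6
#>   term      estimate conf.low conf.high std.error estimate_mean
#>   <chr>        <dbl>    <dbl>     <dbl>     <dbl>         <dbl>
#> 1 intercept    0.298    0.203     0.459    0.204          0.306
#> 2 week         1.01     0.900     1.12     0.0566         1.01
#> 3 os_ios       0.969    0.443     2.16     0.384          1.04
```

The intercept row says a reference participant missed ~30% of expected
GPS groupings at week 0 (truth: 30%). With only 24 participants the
iOS rate ratio (truth 0.7) is weakly identified — its 95% credible
interval spans 0.44-2.2, which is exactly what the replicate recovery
harness (`run_recovery()`) quantifies at scale. `glance(fit)` adds the
random-effect SDs, shape `omega`, Bayes R², WAIC/LOO and the
convergence flag; `build_fixed_effects_report()` /
`build_random_effects_report()` produce publication-shaped tables, and
`autoplot(fit)` a forest plot.

A single-command pipeline (`run_pipeline()`) chains
segment → panel → filter → fit → reports with a manifest, and
`inst/cli/dutymiss.R` exposes `simulate` / `panel` / `fit` / `report` /
`recovery` subcommands for shell use.

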