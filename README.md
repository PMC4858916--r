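# leisuretrips

Objective measurement of children's transport in leisure time from
combined GPS + accelerometer data, with concurrent-validity statistics
against travel diaries and mixed-model associations with parental
perceptions of the neighbourhood environment.

Self-reports of how much 10–12-year-olds walk or cycle outside school
hours are unreliable — children forget short active trips while reporting
car rides fairly well. Wearing a GPS logger and a hip accelerometer for a
week lets transport be measured objectively: both devices record every
15 s, and trips can be detected and classified from speed. This package
implements that full measurement-and-analysis chain for researchers in
physical-activity epidemiology:

* **Epoch alignment** — GPS fixes and accelerometer counts floored to a
  shared 15-s grid; speed recomputed from consecutive fixes when the
  device column is missing (GPX accepted).
* **Wear rules** — non-wear = runs of ≥ 60 min of zero counts; a valid
  day needs ≥ 9 h of simultaneous wear + fix coverage (day 1 excluded);
  inclusion needs ≥ 4 valid days with ≥ 1 weekend day.
* **Trip engine** — a trip is a continuous period of movement in one mode
  lasting ≥ 3 min, tolerating stationary pauses ≤ 5 min; mode from speed
  bands (walking 1–<10, cycling 10–<25, passive ≥ 25 km/h) applied to the
  median trip speed, with running-median smoothing and band-change
  hysteresis.
* **Leisure segmentation** — everything outside each school's own hours
  (Wednesday ends at noon) plus whole weekend days, with home↔school
  commutes excluded by geofencing; outcomes are trips/day, min/day and
  min/trip per mode, stratified week/weekend.
* **Validity statistics** — Pearson r (low ≤ 0.30 / moderate / high >
  0.50) and paired t-tests, GPS vs diary and week vs weekend, including a
  summary-statistics t form

  t = (M₁ − M₂) / √((SD₁² + SD₂² − 2 r SD₁SD₂)/n)

  for checking published tables.
* **Environment scoring** — seven walkability subscales from the parental
  questionnaire, including the weighted residential density score
  q1a + 12·q1b + 25·q1c, plus Cronbach's alpha.
* **Association models** — Gaussian-identity and Gamma-log mixed models
  and two-part hurdle models (logistic "any trip" + Gamma-log "amount
  among engagers"), all with class-level random intercepts; the logistic
  and Gamma parts are fitted by the package's own adaptive Gauss–Hermite
  quadrature engine (25 points by default), reporting OR / exp(b) with
  Wald 95% CIs, with AIC-based family selection.
* **Synthetic studies** — `simulate_study()` generates a full cohort
  (trips, pauses, dropouts, 2.9-m positional noise, non-wear blocks,
  school commutes, under-reported diaries, questionnaires) with a
  ground-truth manifest, so the entire chain is testable end to end.

## Worked example

Simulate a small cohort, run the measurement chain, and compare GPS with
the diary:

```r
library(leisuretrips)

sim <- simulate_study(synth_config(n_participants = 12, n_classes = 4, seed = 7))
ep  <- align_epochs(sim$gps, sim$accel, sim$study_config)
wd  <- flag_valid_days(ep, sim$study_config)
inc <- include_participants(wd, sim$study_config)
tr  <- detect_trips(ep, sim$study_config)
lt  <- filter_leisure_trips(tr, wd, sim$study_config)
out <- compute_outcomes(lt, wd, inc)
cc  <- compare_table(out, compute_diary_outcomes(sim$diary, wd, inc))$comparisons
subset(cc, comparison == "gps_vs_self")
```

```
    mode stratum  n mean_1 mean_2 pearson_r      t     p
    walk    week 11  4.636  0.977     0.714 11.424 0.000
    walk weekend 11  1.909  0.591     0.937  2.844 0.017
   cycle    week 11  1.364  0.205     0.440  4.224 0.002
   cycle weekend 11  1.091  0.318     0.847  2.833 0.018
 passive    week 11  1.409  1.500     0.970 -0.841 0.420
 passive weekend 11  3.182  3.091     0.959  0.516 0.617
```

`mean_1` is GPS-determined and `mean_2` self-reported trips/day: the
children under-report walking and cycling massively (GPS ≫ diary,
p < 0.05) while passive transport is reported accurately (t ≈ 0) —
the pattern that motivates GPS measurement in the first place.

A hurdle model with known truth (odds ratio 1.8, exp(b) 1.3) recovers its
coefficients:

```r
set.seed(1)
d <- simulate_hurdle_data()        # 25 classes x 20 children
fit_hurdle(y ~ x, d)
```

```
Two-part hurdle model for y

-- Logit part (odds of engaging) --
Environment-association fit: binomial_logit ( logit )
  n = 500 | logLik = -329.578 | AIC = 665.156
    predictor estimate ci_low ci_high scale
1 (Intercept)     1.16  0.957    1.42    OR
2           x     1.68  1.387    2.04    OR

-- Positive part (amount among engagers) --
Environment-association fit: gamma_log ( positive )
  n = 269 | logLik = -454.096 | AIC = 916.192
    predictor estimate ci_low ci_high scale
1 (Intercept)     2.02   1.76    2.33 exp_b
2           x     1.27   1.16    1.38 exp_b
```

`run_pipeline()` orchestrates everything from input files to output
tables; `inst/scripts/leisuretrips-cli.R` is a thin command-line wrapper
with `simulate`, `all` and `demo` subcommands and flags for every
threshold.

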