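---
title: "Measuring children's leisure-time transport from combined GPS and accelerometer data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring children's leisure-time transport from combined GPS and accelerometer data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`leisuretrips` implements a complete measurement-and-analysis chain for
studying how much 10--12-year-old children walk, cycle and travel by vehicle
in their leisure time, and how that behaviour relates to parental
perceptions of the neighbourhood environment. Children wear a GPS logger
and a hip accelerometer for a week; the devices record every 15 seconds;
parents and children keep a travel diary and the parents answer a
walkability questionnaire. This vignette explains the models and rules
implemented by the package, the parameters that matter, what the synthetic
generator does and does not emulate, and the design decisions taken where
the measurement protocol leaves room.

## From device streams to epochs

Both devices sample on a nominal 15-s cycle but are not synchronized, so
both streams are floored to a shared 15-s grid (`align_epochs()`). Flooring
rather than rounding follows the epoch-start convention and is
deterministic. The aligned table keeps one record per grid point covered by
either stream; a GPS-only epoch has missing counts and an
accelerometer-only epoch has missing coordinates and speed. Speed comes
from the device column (Qstarz loggers report Doppler speed); when a fix
exists without speed -- common in GPX exports -- it is recomputed as
great-circle distance over elapsed time between consecutive fixes. The
pipeline assumes one study-local timezone and synchronized device clocks;
clock drift between devices is not modelled.

## Wear time, valid days and inclusion

Non-wear time is any run of at least 60 min of consecutive zero
accelerometer counts (`detect_non_wear()`). The rule is applied strictly,
with no tolerance for brief movement spikes inside the window: the plain
60-min zero-run rule is the protocol's definition and spike tolerances
would add a free parameter. The boundary is inclusive -- exactly 60 min of
zeros is non-wear.

A *valid day* needs at least 9 h in which the accelerometer is worn **and**
a GPS fix exists simultaneously (`flag_valid_days()`). The conjunctive
reading is deliberate: transport classification needs both sensors at once,
and an either-device rule would count long indoor periods without location
as measurement time. Each participant's first calendar day is always
invalid because instruments are handed out during that day. Participants
enter the analysis with at least 4 valid days including at least one
weekend day (`include_participants()`). A "day" is a local calendar date
and weekend means Saturday/Sunday -- the simplest defensible conventions.

## Trip detection and mode classification

A *trip* is a continuous period of movement in a single transport mode
lasting at least 3 min, tolerating internal stationary periods of at most
5 min. Epoch speeds are banded:

| band       | speed (km/h)    |
|------------|-----------------|
| stationary | < 1, or no fix  |
| walking    | 1 to < 10       |
| cycling    | 10 to < 25      |
| passive    | >= 25           |

`detect_trips()` proceeds in five steps. (1) Speeds are smoothed by a
5-epoch (75 s) running median; a single-epoch speed spike caused by the
device's few-metre positional error cannot survive a median of five, while
genuine accelerations do. (2) Epochs are banded; missing fixes count as
stationary, so GPS dropouts up to the pause allowance are bridged and
longer dropouts end the movement run (a conservative choice: a long signal
loss may hide anything). (3) Moving epochs chain into movement runs across
stationary gaps of at most 5 min (inclusive). (4) A run splits where a
*different* band persists for at least 4 consecutive moving epochs (1 min).
The persistence rule is the package's disambiguation of "same mode of
transportation": an epoch-level band flicker -- a cyclist slowing through
the walking band -- must not fragment a trip, while a genuine mode change
(walk to bus) must split it. Persistence is counted over the run's moving
epochs, so a flicker interrupted by a short pause does not restart the
count. (5) Segments whose total span, pauses included, is under 3 min are
discarded; the 3-min minimum is duration-based to match the diary
instruction to record trips of at least 3 min. Each surviving segment
becomes a trip whose mode is the band of the *median* smoothed speed over
its moving epochs -- robust to residual flicker.

The same semantics are encoded twice in the test-suite: the vectorized
implementation and an explicit state-machine reference, compared exactly on
hundreds of randomized streams.

## Leisure time and school-trip exclusion

Leisure time is the whole day on weekends and, on school days, everything
before school start and after school end; each school's own schedule is
used, and Belgian primary schools end at noon on Wednesdays, so Wednesday
afternoons are fully leisure. A trip belongs to the window containing its
temporal midpoint, so a trip straddling the school-end boundary is counted
exactly once. Home--school commutes are identified geometrically: one trip
endpoint inside the home geofence and the other inside the school geofence,
in either direction. The geofence radius defaults to 100 m -- generous
against the 2.9-m device error and wide enough to absorb schoolyard and
driveway extent. Commutes are excluded unconditionally, weekends included,
because a trip between home and school is school transport regardless of
the day.

Outcomes (`compute_outcomes()`) are per-participant trips/day, minutes/day
and minutes/trip for each mode, stratified into week and weekend days.
Averages divide by *valid* days in the stratum, not all observed days;
diary outcomes use the same denominators so the two instruments are
comparable (`compute_diary_outcomes()`).

## Concurrent validity statistics

GPS-vs-diary agreement is summarized per mode and stratum by Pearson
correlations (classified low <= 0.30, moderate 0.31--0.50, high > 0.50,
boundaries handled exactly) and paired t-tests, all two-sided at alpha =
0.05 (`compare_table()`). The paired t is implemented both from raw paired
data and from summary statistics,

$$t = \frac{M_1 - M_2}{\sqrt{(SD_1^2 + SD_2^2 - 2\,r\,SD_1 SD_2)/n}},$$

which are algebraically identical (tested to 1e-10); the summary form lets
published tables be checked without raw data. Participants missing one side
of a comparison are dropped pairwise for that row.

## Environment scoring

The parental questionnaire yields seven subscales. Residential density
weights the three dwelling-type frequency items (5-point none-to-all scale,
coded 0--4 so that "none everywhere" scores zero):
`q1a + 12*q1b + 25*q1c`, up-weighting row houses and apartments relative
to single-family homes. The other six subscales are item means on the
1--4 agreement scale; a subscale tolerates missing items while at least
half are answered, standard questionnaire practice. Item sets are
configurable by column naming (`<subscale>_<index>`) since instruments
differ between studies. `cronbach_alpha()` reports internal consistency.

## Association models

The analysis relates the seven environment scores to each transport
outcome with two-level models (children within school classes), always
adjusting for age, sex, SES, school and wear time; all seven scores enter
jointly, as result tables that print one coefficient per subscale imply a
multivariable model.

* **Gaussian identity** (`fit_gaussian()`), for approximately normal
  outcomes such as weekday walking: a linear mixed model fitted by maximum
  likelihood via `lme4::lmer`, reporting beta with Wald 95% CIs.
* **Gamma log** (`fit_gamma_log()`), for positive skewed outcomes:
  reported as exp(b), the proportional change in the outcome per one-unit
  increase in a predictor.
* **Two-part hurdle** (`fit_hurdle()`), for zero-heavy outcomes such as
  the weekend strata: a mixed logistic model for engaging at all (odds
  ratios) over everyone, and a mixed Gamma-log model for the amount among
  engagers.

The Gamma and logistic mixed models are fitted by the package's own
adaptive Gauss--Hermite quadrature engine (`agq_glmm()`): the scalar
random intercept is integrated out per cluster with nodes re-centred at
the cluster's posterior mode and re-scaled by the curvature there, 25
points by default, and the marginal likelihood is maximized jointly over
the fixed effects, the random-intercept SD and the Gamma shape. Numerical
choices that matter: predictors are standardized internally (the optimiser
and the finite-difference Hessian work on O(1) parameters; estimates are
mapped back), the inner mode-finding is plain Newton (the integrand is
log-concave for both families), confidence intervals are Wald on the link
scale then exponentiated, the Gamma dispersion is estimated by full ML
consistent with the fitting principle, and non-convergence triggers up to
five restarts -- continuing from the current point when the optimiser
merely ran out of iterations, jittered otherwise. A random-intercept SD
estimated at numerically zero is refitted as the fixed-effects model and
flagged singular, the standard treatment of boundary fits. The engine is
cross-checked in the tests against `lme4::glmer` at 25 quadrature points
and against brute-force numerical integration of the marginal likelihood;
refining 25 to 101 points moves well-conditioned estimates by less than
1e-4. Model families are compared by AIC (`select_family_by_aic()`);
`fit_all_models()` uses the hurdle automatically when an outcome has more
than 5% zeros.

## The synthetic-data generator

`simulate_study()` creates a full cohort with a ground-truth manifest so
every stage is testable without any real data. Its defaults are the study
conditions the package targets: 126 children in 8 classes at 4 schools
(urban and suburban), 7 consecutive days starting on a Monday (hence two
weekend days) in winter, 15-s epochs, and a 2.9-m positional noise SD
matching the logger's median dynamic error. Leisure trips are home-based
excursions (out, dwell, return) placed by a thinned Poisson process inside
leisure windows; mean rates and durations per mode and stratum default to
the GPS-observed levels in this population (e.g. walking 3.96 trips/day on
weekdays, passive transport 2.12 trips/day on weekends). Engagement gates
(the probability of any trip of a mode in a stratum) produce the zero
inflation that motivates the hurdle models. Epoch speeds are drawn per
mode and clipped inside the mode's band by default (leakage is
configurable); pauses of 1--4 min occur inside trips with probability 0.3;
a per-epoch 5% GPS dropout and Doppler-grade speed noise (SD 0.5 km/h --
device speed is far less noisy than position) complete the noise model.
Positional noise is isotropic Gaussian in a local metric projection,
matching a scalar error figure. School commutes run along the exact
home--school line on every school day covered by wear time, with walking
or cycling as the commute mode (homes lie 700--1800 m from school, so a
vehicle commute could not satisfy both its speed band and the 3-min
minimum at realistic distances). Non-wear blocks of 60--110 min are
injected into wear time; 15% of children are low-compliers who fail the
inclusion rule, yielding realistic attrition.

The diary model reports each true trip independently with probability 0.2
(walking), 0.2 (cycling) and 0.9 (passive) -- children forget short active
trips far more than car rides. Pure thinning at 0.9 would still leave a
systematic deficit that becomes statistically significant at cohort size,
whereas children actually report passive travel about as often as they
over-report it; the generator therefore adds phantom passive diary entries
at 0.2/day so the passive diary is unbiased on average while the active
modes stay heavily under-reported. Questionnaire items are generated from
latent subscale values, and configurable coefficients link the scores to
trip rates (log-linear) and engagement (logistic) with class-level random
intercepts; the default coefficients are zero. `simulate_hurdle_data()`
generates two-part model data directly from known coefficients for
recovery studies.

What the generator does *not* emulate: street-network routing (trips are
straight lines), behaviourally realistic activity scheduling, seasonal and
weather effects, device clock drift, and the 20--25% trip
misclassification of production GPS-processing software. Passing tests
therefore demonstrate that the chain is correct under its stated rules and
robust to device-grade noise -- not that those rules are free of
misclassification on real streets.

## Problem sizes and runtime choices

The test-suite exercises the trip engine against its brute-force reference
on 500 random streams of up to 2,000 epochs, non-wear detection against a
window-scan oracle on 1,000 streams, exact recovery on a 10-child
noise-free cohort, noisy recovery and the diary direction checks on a
60-child cohort, and hurdle-model recovery on 100 replicates of 25 classes
x 20 children -- sizes chosen so the whole suite completes in minutes
while keeping every estimate's Monte-Carlo error well below the tolerance
it is tested at. The acceptance script simulates the full 126-child cohort.

## Known limitations

Trip-edge hysteresis is minimal: a trip begins at its first and ends at
its last moving epoch, so a dropout exactly at a boundary can shift an
endpoint by an epoch. The wear-time covariate enters the models as mean
minutes/day over valid days (hours would only rescale its coefficient).
GPS-only wear (device worn, no fix) is not imputed. The hurdle parts are
fitted independently, which is exactly right when the two processes share
no parameters, but no cross-part correlation is modelled.
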