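---
title: "Measuring felid temporal activity from fused GPS and accelerometer data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring felid temporal activity from fused GPS and accelerometer data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lunardiel)
```

## The problem

Two similarly sized felids sharing one landscape — a strictly protected
nocturnal specialist ("ocelot-like") and a widespread generalist
("bobcat-like") — may coexist by being active at different times. Testing
that idea requires a continuous, individual-level measure of movement
rate and a principled way to relate it to the drivers of the diel cycle:
sun altitude, lunar illumination, and daytime heat.

GPS collars give an unbiased movement rate (straight-line distance
between consecutive fixes divided by the time lag) but only while the
collar is on a high-frequency schedule; battery budgets confine such
schedules to windows around full and new moons, plus daily anchor fixes.
Bi-axial accelerometers record activity counts continuously at almost no
battery cost, but in arbitrary units. `lunardiel` implements the fused
analysis: calibrate counts against GPS-derived velocity, predict velocity
wherever GPS is silent, and model the combined series against
astronomical and thermal covariates with an AR1 mixed model.

## Pipeline stages and their assumptions

1. **Trajectory.** Fixes with HDOP above 10 are censored (the boundary
   value is kept), then only consecutive pairs 25–35 minutes apart are
   retained as "high-frequency". Velocity is the haversine distance on a
   6,371,000 m sphere divided by the lag in hours; at sub-kilometre step
   lengths the sphere-vs-ellipsoid error is far below GPS jitter. Whether
   a planar or geodesic distance is used is immaterial at this scale; the
   haversine choice is documented here once.
2. **Fusion.** Each velocity record is attributed with the minimum,
   maximum, mean and *sample* variance (n−1) of the six 5-minute
   bi-axial activity reports in the trailing half-open window
   (t−30 min, t]; windows with fewer than six reports are missing data,
   not errors. A 1,000-tree random-forest regression (floor(p/3) = 2 of
   the 8 features tried per split) maps features to velocity. Because the
   ensemble averages training-leaf means, predictions are bounded by the
   training-target range — predictions can never extrapolate. Individuals
   whose collars show repeated high-velocity movements with cohort-low
   activity (at least 3 intervals above the 0.9 velocity quantile and
   below the 0.1 activity quantile) are treated as accelerometer
   malfunctions and excluded from training; the field description of this
   screen is qualitative, so the quantile/min-event quantification here
   is this package's own. Both resubstitution and out-of-bag accuracy are
   reported and labelled, since a resubstitution R² flatters any forest.
3. **Ephemeris.** Sun altitude, moon altitude and the illuminated
   fraction come from compact analytic theories (a Meeus-style solar
   position and a truncated lunar series with a single altitude-parallax
   correction), computed in UTC for one study site. No atmospheric
   refraction is applied: the categorization thresholds (±13.5°, horizon
   crossing) sit far from the ~0.5° refraction scale. Whether a
   topocentric or geocentric lunar altitude is intended by upstream
   conventions is ambiguous; the package uses topocentric and the test
   tolerance for the moon is widened to 1° accordingly. Test-suite
   accuracy against an independently implemented reference (Michalsky
   solar algorithm; Astronomical Almanac low-precision lunar series) over
   1,000 random instants in 2010–2030: sun ≤ 0.5°, moon ≤ 1°, fraction
   ≤ 0.02, with historical eclipse instants as absolute anchors.
4. **Categorization.** Day is sun altitude > +13.5°, Night < −13.5°,
   Crepuscular otherwise (boundaries inclusive to Crepuscular). Moon
   phase is Full when the illuminated fraction is ≥ 0.9 *and* the moon is
   above the horizon, Dark when the fraction is < 0.1 *or* the moon is at
   or below the horizon, Mid otherwise; an altitude of exactly 0 counts
   as "not above", keeping Full strictly above-horizon (the rule text
   leaves 0 unassigned). The merged LunarDiel factor crosses moon phase
   with Night and Crepuscular only and collapses all Day records to a
   single level — 7 levels total. Season is Hot iff TMAX ≥ 33 °C, the
   upper bound of the ocelot thermoneutral zone, joined on the record's
   *local civil date* (fixed UTC−6 by default, configurable).
5. **Velocity standardization.** Movement-rate baselines differ between
   species, so velocity is standardized per species. Centring raw
   velocity before a log transform is undefined for sub-mean values;
   the package therefore applies `log(1 + v)` first and then centres and
   scales to unit variance within species. This order is a deliberate
   design decision, flagged here; no claim is made about how any
   particular field dataset handled it, and zero velocities are handled
   by the +1 offset.
6. **Inference.** Nine exploratory models over the continuous drivers
   (SunAlt; MoonIlluminatedFrac; TMAX; the three additive combinations
   containing SunAlt; and three interactive expansions up to the full
   three-way product) are fit per species by maximum likelihood and
   ranked by AIC. The final model is the full factorial
   LunarDiel × Season × Species. All fits share the same covariance
   structure: independent random intercepts for individual and for
   provenance Type (True vs Predicted velocity), crossed, plus an AR1
   residual correlation indexed by observation order within individual.

## The AR1 mixed model

The marginal model is y ~ N(Xβ, σ²(R(φ) + Z G Zᵀ)) with R block-diagonal
AR1 per individual. β and σ² are profiled analytically; the remaining
1–3 parameters (Fisher-z of φ, log variance ratios) are optimized by
L-BFGS-B from three fixed starting points with relative tolerance 1e-8,
so the fit is deterministic. All solves use the sparse tridiagonal AR1
inverse and the Woodbury identity, giving O(n) cost; the test suite pins
the structured log-likelihood against a dense multivariate-normal
construction of the same covariance to 1e-8 on small instances, and
against `nlme::lme` where the models coincide (single random effect).

Numerical conventions, each deliberate:

* AR1 is indexed by observation *order* within individual, not elapsed
  time, matching the discrete-lag convention of the standard
  mixed-model software; a mixed 5-min/30-min cadence is therefore
  treated as consecutive observations. This is a documented limitation,
  not an oversight.
* The individual and Type intercepts are crossed and independent (the
  nesting is not identifiable from the description of the original
  software setup); a two-level Type component can sit on the zero
  boundary, in which case the fit warns and reports it.
* Model df counts every estimated parameter: fixed effects + σ² + φ +
  one per random component. AIC = −2 logLik + 2 df.
* The likelihood and AIC use the ML residual variance (RSS/n); standard
  errors, t statistics and intervals use the df-adjusted scale
  (RSS/(n−p)) with residual df n − rank(X), the convention of `nlme`
  even under ML.

Estimated marginal means average the model-matrix rows of the full
factor grid with equal weights over factors not in the requested grid,
numeric covariates held at their sample means; cells touching aliased
coefficients (empty data cells) are flagged non-estimable rather than
dropped. Pairwise contrasts within a family of k means use the
studentized-range (Tukey) adjustment via `ptukey`; the tests check it
against a direct numeric integration of the studentized-range
distribution. Two contrast families mirror the scientific questions:
time periods within a species, and species within a time period.

## What the synthetic generator emulates

The generator exists so every stage can be tested against known truth:

* **Latent velocity** at 5-minute steps:
  baseline × diel multiplier × lunar modulation (nocturnal only, via
  exp(effect × illuminated fraction) when the moon is up) × heat
  suppression (diurnal only, when TMAX ≥ 33 °C), times a log-normal AR1
  innovation (φ = 0.6 at 5-min steps, marginal SD 0.45). The AR1-on-log
  choice reflects the first-order autoregressive character of real
  activity-count series while keeping velocity positive.
* **Positions** follow a correlated random walk whose step lengths match
  the latent velocity (heading increments SD 0.4 rad), with 15 m GPS
  jitter; HDOP is a shifted gamma calibrated so ~5% of draws exceed 10,
  exercising the censoring path. No published error model was available
  to copy, so these are design values.
* **Collar schedules**: continuous 30-min fixes, or daily noon/midnight
  anchors plus 24-h or 72-h high-frequency windows centred on each full
  and new moon, the moon instants coming from the package's own
  ephemeris rather than an external almanac.
* **Accelerometer counts** are a saturating map
  255·(2/π)·atan(v / 400) of latent velocity — monotone, as the strong
  positive velocity–activity relationship requires, but bounded at 255
  as the hardware is — plus AR1 noise shared between the axes; the noise
  defaults (SD 12, shared fraction 0.5) put the between-axis rank
  correlation near 0.96. A "malfunction" flag replaces the velocity
  input with an unrelated low-level process, decoupling counts from
  movement for censoring tests. Real collars aggregate 4 Hz
  acceleration differences into each 5-minute report by an unpublished
  rule; the generator emits the 5-minute values directly.
* **Weather** is a shared sinusoidal seasonal cycle plus correlated
  daily anomalies, with the anomaly correlation solved so the overall
  TMAX/TMIN Pearson correlation targets 0.85 over a full seasonal
  cycle; short extracts realize less, since the shared seasonal
  variance is truncated.
* The default cohort is 8 nocturnal-archetype and 6
  crepuscular-archetype individuals on mixed schedules — the deployment
  structure this analysis is designed around.

What it does **not** emulate: home-range geometry, habitat selection,
inter-individual interaction, denning behaviour, fix-failure gaps, or
cloud cover modulating lunar illumination. A pipeline that passes these
tests is verified as *machinery*; field data can still violate the
generative assumptions (e.g. activity without displacement).

## Problem sizes used by the tests and scripts

Simulation-backed checks run at desk scale, chosen as the smallest sizes
at which each property is comfortably detectable: fusion checks use 3
individuals × 14–18 days; the ordering-recovery study uses 20 replicates
of 12 GPS-continuous individuals × 32 days starting 20 April (two full
moons in window, daily TMAX straddling 33 °C), about 15,000–17,000
velocity records per replicate; the Breusch–Pagan calibration uses 200
replicates at n = 500. The recovery study deliberately uses GPS-only
cohorts: the inference path being tested (categorize → AR1 LMM →
marginal-means orderings) is identical, and a fused-cadence cohort of
the same record count would add only random-forest runtime.

## Known limitations

* The AR1-by-order convention misstates the correlation across the
  True/Predicted cadence boundary in fused series.
* The Type random intercept has two levels; its variance is weakly
  identified and often boundary-valued — it is retained by design and
  reported with a warning, and can be dropped via `type = NULL`.
* The ephemeris is a low-precision theory: adequate for 13.5° thresholds
  and 0.9 illumination cuts, not for eclipse-grade work.
* Marginal means use residual df throughout; no Satterthwaite or
  Kenward–Roger correction is attempted.
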