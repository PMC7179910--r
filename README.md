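# lunardiel

Temporal activity of sympatric felids from fused GPS + accelerometer
biologging.

## The problem

Ecologically similar carnivores sharing one landscape — here a nocturnal
ocelot-like specialist and a crepuscular bobcat-like generalist — may
coexist by partitioning the *time* axis rather than space or diet.
Testing that requires a near-continuous, individual-level movement rate
and a model linking it to the drivers of the diel cycle. GPS collars
yield an honest movement rate (straight-line distance between
consecutive ~30-min fixes ÷ time lag, with HDOP > 10 and
non-high-frequency fixes censored) but only inside battery-limited
schedule windows; bi-axial accelerometers record activity counts (0–255,
every 5 min) continuously but in arbitrary units.

`lunardiel` implements the fused analysis end to end:

1. **True Velocity** from censored GPS fix pairs (haversine, m/hr).
2. **Predicted Velocity** from a 1,000-tree random-forest regression of
   velocity on 8 accelerometer window features — min, max, mean, sample
   variance of the six 5-min reports per axis in the trailing 30-min
   window — with malfunction screening, OLS validation of predicted vs
   true, a studentized Breusch–Pagan heteroscedasticity check, and
   interaction checks against potential confounders.
3. **Velocity Combined**: True where available, Predicted elsewhere,
   provenance kept in a `Type` field.
4. **Covariates**: sun altitude, moon altitude and lunar illuminated
   fraction from a built-in analytic ephemeris; daily TMAX joined on the
   local civil date; per-species standardized `log(1+v)` velocity.
5. **Categorization**: Diel (Day / Night / Crepuscular at ±13.5° sun
   altitude), MoonPhase (Dark / Mid / Full at 0.1 / 0.9 illumination
   with the moon above the horizon), the 7-level LunarDiel merge, and
   Season (Hot iff TMAX ≥ 33 °C).
6. **Inference**: linear mixed models fit by ML with crossed random
   intercepts (individual, Type) and AR1 residual correlation — a
   9-model exploratory set over the continuous drivers ranked by AIC,
   then the final `LunarDiel × Season × Species` factorial — followed by
   estimated marginal means (equal-weight reference grid, covariates at
   their means) and Tukey-adjusted pairwise contrasts in two families:
   time periods within a species, and species within a time period.

The mixed model is y ~ N(Xβ, σ²(R(φ) + ZGZᵀ)), with β and σ² profiled
analytically and the variance parameters optimized on transformed scales
via sparse AR1-inverse/Woodbury algebra (O(n) per evaluation). The test
suite pins it against a dense multivariate-normal oracle (1e-8),
`nlme::lme` where the models coincide, and the `emmeans` package for the
marginal means.

A first-class synthetic-data generator produces cohorts with known
activity drivers (diel multipliers, lunar modulation, heat suppression,
AR1 log-normal noise), correlated-random-walk GPS tracks with HDOP and
jitter, lunar-window or continuous collar schedules, saturating
bi-axial accelerometer counts, and seasonally correlated TMAX/TMIN
weather — so every stage is testable against ground truth. See
`vignettes/methods.Rmd` for the model, its assumptions, and every
numerical convention.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → fuse → categorize → select → contrast → recover), writing
its tables under `results/`. Running it end to end:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

prints, among other things (14 simulated individuals, 40 days, one
injected accelerometer fault):

```
True Velocity records after censoring: 8230
censored from training: B06
<velocity_model> 1000 trees, 2 vars/split
  OOB variance explained: 83.8%  OOB RMSE: 63.16
  resubstitution R2: 0.9687  RMSE: 28.47
validation: slope 0.930, R2 0.9687, BP = 683.96 (p = 9.2e-151, df = 1)
added variance from a Species interaction: 0.027%
Velocity Combined: 149806 records ( 8230 True / 141576 Predicted )
```

The injected fault (B06) is the only flagged collar; the Breusch–Pagan
test rejects homoscedasticity (variance grows with velocity, as
expected for activity data); and the Species interaction adds
essentially nothing — the activity→velocity map transfers across
species. Model selection then picks the full interactive model for both
species (`model 9`, ΔAIC ≥ 6 over the runner-up), and the final
marginal means recover the generated ecology, e.g. for the cool season:

```
       LunarDiel          Season Species  emmean   lower.CL upper.CL
 Dark Moon Night           Cool  ocelot   0.4188    0.347    0.491
 Full Moon Night           Cool  ocelot   0.2404    0.159    0.322
             Day           Cool  ocelot  -0.2438   -0.314   -0.174
```

(ocelot nocturnal with a dark-moon boost; the hot-season table shows the
diurnal heat suppression), with Tukey-adjusted species contrasts
significant in the generated directions — ocelots over bobcats on dark
nights, bobcats over ocelots in daylight. The recovery study
(`analysis/06_recovery_study.R`) repeats this over 20 seeded cohorts:
all six generated orderings are recovered with the correct sign in 100%
of replicates (mean n ≈ 16,600 records).

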