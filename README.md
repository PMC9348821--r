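# dielstarch

Quantitative analysis of diel starch turnover and circadian transcript
rhythms in plant time-series experiments.

Arabidopsis plants accumulate starch through the day and mobilize it at
night at a nearly constant rate that is paced so reserves run out close to
the anticipated dawn — even in light–dark cycles shorter or longer than
24 h. Testing how tightly this pacing, and the clock transcripts behind it,
track dawn versus dusk requires a consistent statistical toolkit for
replicate diel time courses: rate estimation, exhaustion-time extrapolation,
shape scoring, and phase/amplitude estimation. `dielstarch` packages those
analyses, tidyverse-style (tibbles in, tibbles out, `tidy()`/`glance()`
methods, `autoplot()`), together with a synthetic-data generator that
emulates the experimental designs so every stage can be exercised without
measured data.

## What it computes

Time is Zeitgeber time (ZT): decimal hours after the most recent dawn, with
dusk at ZT *P* (the photoperiod) and the cycle length *T* (T17, T24, T28
cycles are all supported).

- **Turnover rates.** Starch accumulation (window [0, *P*]) and
  mobilization ([*P*, *T*]) rates as OLS slopes over raw replicate
  (zt, value) pairs — replicates are never pre-averaged — with
  *t*-based 95% CIs; optional normalization to the mean dusk content
  (relative rates, h⁻¹). Between-genotype rate differences are tested by
  ANCOVA (`value ~ group × zt`, type III SS). For cross-T-cycle
  comparisons the mobilization window can be capped at dusk + 8.5 h (a T17
  night) so the *initial* rate is compared over the same span of darkness.
- **Starch exhaustion time.** StEx: the root f(ZT) = 0 of the night
  regression line, found by a bracketed derivative-free root finder, with a
  delta-method SE from the slope/intercept covariance. Apparent StEx
  (StEx^app): nested dusk-anchored fits over 3, 4, … consecutive time
  points (within the 8.5-h cap), each extrapolated to zero, aggregated as a
  geometric mean with a log-scale Student-t 95% CI.
- **Nonlinearity score.** A chord is drawn from the mean dusk to the mean
  dawn starch content; each time point's residue (observed − predicted)/
  predicted is averaged. Zero means linear mobilization; negative means
  too-fast-early; positive too-slow-early. 95% CIs by nonparametric
  bootstrap over replicates within time points; groups compared by one-way
  ANOVA + Tukey HSD letters.
- **Transcript rhythm features.** Peak time from bootstrapped series via
  AICc-selected polynomial (degree 2–6) and smoothing-spline fits (50
  draws per method), circular-mean aggregated with a percentile CI, robust
  to peaks that wrap around dawn; amplitude as max − min of the time-point
  means with Gaussian error propagation of the two SEMs.
- **Dawn/dusk alignment (DIST/NORM).** Profiles from different
  photoperiods are anchored to dawn or dusk, interpolated onto their shared
  offset grid, and compared by Euclidean distance (DIST) and by distance
  divided by its propagated error (NORM), min–max scaled to [0, 1] across
  an experiment; a two-way type II ANOVA (`value ~ treatment × offset`)
  tests whether series desynchronize on a given time base.
- **Arithmetic-division bookkeeping.** Under R = S/T (mobilization rate =
  dusk starch / time to anticipated dawn), `required_rate_ratio()` gives
  the rate change a dusk perturbation demands — e.g. a 4-h early dusk in a
  12-h photoperiod leaves 2/3 of the starch and a 16-h night, so a 50%
  slowdown is required.

The generator (`simulate_starch()`, `simulate_transcript()`,
`apply_perturbation()`) produces piecewise-linear starch trajectories with
a curvature knob for night shape, raised-cosine transcript bumps with
controllable peak, width and damping, and early-dusk / low-light-day
perturbations, on any photoperiod/T-cycle grid.

## Worked example

Simulate one genotype in a 12-h photoperiod whose mobilization is slightly
fast-early (curvature 1.4), then ask when starch would run out and how
nonlinear the night is:

```r
library(dielstarch)

regime <- light_regime(cycle_length_h = 24, photoperiod_h = 12, irradiance = 160)
starch <- simulate_starch(
  starch_model(accum_rate = 1, exhaustion_zt = 24, curvature = 1.4,
               noise_frac = 0.05, n_reps = 4),
  regime, seed = 42)

mobilization_rate(starch)
#> <slope_fit> slope -1.008 +/- 0.0441 (95% CI -1.099 to -0.9175), n = 28, window ZT12-ZT24
stex(starch)
#> <exhaustion_estimate> StEx = 23.048 h after dawn (SE 0.282)
stex_app(starch)
#> <exhaustion_estimate> StEx_app = 21.281 h after dawn (95% CI 20.374-22.229, n = 3 fits)
nonlinearity(starch, n_boot = 1000, seed = 1)
#> <nonlinearity_result> score = -0.2129 (95% CI -0.2656 to -0.1556, 1000 bootstrap draws), 5 interior points
```

The whole-night regression projects exhaustion at ZT23.0, but the nested
dusk-anchored fits — which capture the *initial* rate before the late-night
shape bends — project ZT21.3, and the negative score (−0.21, CI excluding
0) flags exactly that fast-early mobilization.

A morning-phased transcript peaking just before dawn:

```r
rve8 <- simulate_transcript(
  transcript_model(baseline = 10, amplitude = 3, peak_zt = 22.3,
                   peak_width = 5, noise_sd = 0.3, n_reps = 3),
  regime, gene = "RVE8", seed = 7)

peak_time(rve8, seed = 8)
#> <rhythm_feature> peak at ZT22.02 (95% CI ZT21.25-ZT22.65, 100 bootstrap peaks)
amplitude(rve8)
#> <rhythm_feature> amplitude 2.941 +/- 0.126 (95% CI 2.591-3.290)
```

The planted peak (ZT22.3) and amplitude (3 log2 units) are recovered within
their intervals despite the wrap-around past dawn.

`run_pipeline()` drives the same stages from a YAML scenario
(genotypes × regimes × variables) and writes per-stage TSVs plus a JSON
summary; `read_diel()`/`write_diel()` define the tidy TSV schema for
measured data, and `reproduce_supplementary()` recomputes the full
statistics bundle from any deposited tables converted to that schema.

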