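---
title: "Models and methods behind dielstarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dielstarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielstarch)
```

This vignette explains the statistical machinery in `dielstarch`: the
models each estimator assumes, the parameters that matter and their
defaults, the numerical choices made where several readings were
defensible, and what the synthetic generator does and does not emulate.

## Time conventions and data model

All time is Zeitgeber time (ZT): decimal hours since the most recent
dawn. Dawn is ZT0, dusk is ZT $P$ (the photoperiod), and the external
cycle has length $T$ (17, 24 or 28 h in the designs we target). A dawn
sample of the following cycle may be recorded at ZT $T$. Data live in a
long tidy table — one row per replicate measurement — because replicate
counts vary between time points (2–7 in the target experiments); see
`read_diel()` for the schema. Two unit conventions are carried:
metabolites in µmol Glc-equivalents g⁻¹ FW and transcripts in
log2(copies × 2.5×10⁷ g⁻¹ FW).

One deliberate convention: the dusk sample belongs to *both* the
light-period and the night fit windows. Accumulation is fitted on the
closed window $[0, P]$ and mobilization on $[P, T]$, so the boundary
point anchors both lines. The same closed-window rule lets an early-dusk
treatment shift the boundary to the perturbed lights-off time.

## Rate estimation

Rates are slopes of ordinary least squares fits of value against ZT over
all replicate pairs in the window — replicates are never averaged first,
so the standard error reflects biological scatter at its true sample
size. The 95% CI is $\hat\beta \pm t_{0.975,\,n-2}\,\mathrm{SE}$.
Relative (dusk-normalized) rates divide every value by the arithmetic
mean of all dusk replicate values of that series before fitting; the
result is in fraction-of-dusk-starch per hour, which is the scale on
which mobilization rates are comparable across conditions with different
dusk contents.

The model is deliberately linear: night-time starch mobilization in
these designs is close to linear for most of the night, and the
scientific quantities of interest (initial rate, projected exhaustion)
are defined *through* the linear fit. Curvature is handled by windowing
and by the nonlinearity score, not by nonlinear regression.

Genotype contrasts use ANCOVA, `value ~ group * zt` with sum-to-zero
contrasts and type III sums of squares (via `car::Anova`); the
group-by-time interaction is the rate difference. We always include the
intercept-difference term, so the test is specifically about slopes.
When both groups carry identical data the residual variance is zero and
the p-value is undefined; `compare_slopes()` reports the (zero)
interaction sum of squares and flags the fit degenerate instead of
returning a spurious probability.

For comparisons across T-cycles, mobilization windows are capped at dusk
+ 8.5 h — the duration of a T17 night — so every cycle is compared over
the same span of darkness (that cap covers 71% of a T24 night and 61% of
a T28 night). The cap also shields estimates from the late-night
slowdown of mobilization seen in long cycles.

## Exhaustion-time extrapolation

**StEx** extrapolates the whole-night regression to zero starch. The
root of $f(\mathrm{ZT}) = b + m\,\mathrm{ZT}$ is located by a bracketed,
derivative-free root finder (`stats::uniroot`, tolerance $10^{-12}$, on
$[\mathrm{dusk}, \mathrm{dusk} + 3T]$). Although the root has the closed
form $-b/m$, the bracketing search also certifies the root lies in a
sensible horizon; a projected root earlier than dusk is flagged
degenerate rather than returned silently. The SE comes from the delta
method on $-b/m$:

$$\operatorname{var}\!\left(-\tfrac{b}{m}\right) =
  \frac{\operatorname{var}(b)}{m^2}
  + \frac{b^2 \operatorname{var}(m)}{m^4}
  - \frac{2b\operatorname{cov}(b,m)}{m^3}.$$

**StEx^app** targets the *initial* mobilization rate. Nested windows all
start at dusk and extend point by point into the night — never fewer
than three time points, never beyond the 8.5-h cap — and each fit is
extrapolated to zero. With 2-h sampling this yields windows of 3, 4 and
5 points (three fits); with 4-h sampling fewer windows exist and
`n_fits` records how many were used. The roots are aggregated as a
geometric mean. The 95% CI is a Student-t interval on the log-scale mean
of the roots, exponentiated: whether the published interval was computed
on the log or raw scale is not determinable from the method description,
and the log scale is the internally consistent companion of a geometric
mean (it also guarantees a positive lower bound). A window whose slope
is non-negative, or whose root falls beyond three cycle lengths, cannot
project exhaustion and is excluded with a warning; if every window is
excluded the series has no estimate.

By construction the geometric mean never exceeds the arithmetic mean of
the roots; the test suite asserts this AM–GM relation on every run as a
cheap internal consistency check.

## The nonlinearity score

A chord is interpolated between the mean dusk and mean dawn starch
contents; at each time point the residue is
$(\text{observed mean} - \text{predicted})/\text{predicted}$, and the
score is the average residue. Negative scores mean mobilization runs
fast early in the night (content dips below the chord), positive scores
slow-early. The default averages over **all** time points, matching the
verbal definition of the procedure; because the two endpoint residues
are identically zero, this equals the interior residue sum divided by
the total number of time points. `include_endpoints = FALSE` averages
over interior points only, which rescales the score by
$(k+2)/k$ for $k$ interior points — useful when the score should be read
as a pure summary of interior shape. Both modes are tested; the choice
only rescales, it never changes sign or ordering.

The 95% CI is a percentile bootstrap resampling replicates within every
time point, endpoints included, so each draw re-anchors the chord — the
uncertainty of the reference line propagates into the interval. If the
dawn mean is zero and the sampling grid touches it, interior predictions
can reach zero; such points are excluded with a warning rather than
dividing by zero. Group comparisons compute one score per complete
replicate profile and run one-way ANOVA with Tukey HSD letters
(Tukey–Kramer on unbalanced groups, via `multcomp::cld`); bootstrap
draws are not used as ANOVA units because they are not independent
observations.

## Transcript peak time and amplitude

Peak time is estimated on bootstrapped series: replicates are resampled
within each time point, and each draw is fitted twice — with polynomials
of degree 2–6 and with smoothing splines over a degrees-of-freedom grid
of 4 … min(10, distinct ZTs − 1) — each selected by minimum AICc,
$\mathrm{AICc} = n\log(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$ with $k$
counting mean parameters plus one for the variance, ties broken toward
fewer parameters. The peak of the selected curve is located by a fine
grid search (0.05 h). We read "peak" as the global stationary maximum of
the fitted curve (or the boundary of the fitting window): a literal
inflexion point (zero second derivative) does not mark a peak.

Peaks near dawn would sit at the edge of a [0, T] window, where
polynomial fits are least trustworthy, so the series is first unwrapped
onto a window starting at three quarters of the cycle (ZT18 in T24) and
running one full cycle — samples before the start are shifted by $T$.
The 100 per-draw peaks (50 per method by default) are combined by a
circular mean on the cycle, with a bootstrap percentile CI on the
circular residuals; an arithmetic mean would be biased for phases
spanning the dawn discontinuity. If the selected curve is monotone over
the window in more than half of the draws, the oscillation is declared
unscorable rather than assigned a meaningless phase.

Amplitude is the difference between the maximum and minimum time-point
means over one full cycle (17/24/28 h as appropriate), with Gaussian
error propagation of the two extreme SEMs,
$\mathrm{SE} = \sqrt{\mathrm{SEM}_{max}^2 + \mathrm{SEM}_{min}^2}$, and
a Student-t 95% CI. A dawn sample recorded at ZT $T$ is folded onto ZT0
first so the same phase is not counted twice.

## Dawn/dusk alignment scores

To ask whether profiles from different photoperiods superimpose better
on a time-since-dawn or a time-since-dusk axis, each series is
aggregated to a mean ± SEM profile and re-anchored: dusk anchoring sets
offset 0 at lights-off and rotates pre-dusk samples into the same cycle.
Because different photoperiods then sample different native offsets,
profiles are linearly interpolated onto the intersection of their offset
ranges at the finest common step; at least three shared offsets are
required.

The DIST score between two profiles is the Euclidean distance of the
mean vectors on the shared grid; its first-order propagated error is
$\sqrt{\sum_j d_j^2(\mathrm{sem}_{aj}^2 + \mathrm{sem}_{bj}^2)}\,/\,\mathrm{dist}$
(the exact gradient of the Euclidean norm — verified in the tests
against a numeric Jacobian), and NORM is distance divided by that error.
With more than two treatments the aggregate is the arithmetic mean of
all pairwise scores; a sum would grow with the number of treatments and
break comparability across experiments of different size. Scores are
min–max scaled to [0, 1] per score type across all
transcript × genotype × anchor combinations of one analysis run, so 0
and 1 mark the best and worst alignment actually observed in that run.

The companion hypothesis test is a replicate-level two-way ANOVA,
`value ~ treatment * offset` with offset categorical on the shared grid
and type II sums of squares. A profile that is merely time-shifted
between treatments keeps its average level, so desynchronization
surfaces in the treatment-by-offset interaction rather than the main
effect; the "aligned" verdict therefore requires both terms to be
non-significant at $\alpha = 0.05$.

## The synthetic generator

The generator reproduces the statistical structure the estimators
assume, not plant physiology. Starch follows a piecewise mean
trajectory: linear accumulation at rate $a$ (µmol g⁻¹ FW h⁻¹) to dusk,
then $S_{dusk}\,(1 - (t-P)/(E-P))^{\gamma}$ to zero at ZT $E$, zero
afterwards. The single curvature knob $\gamma$ exercises the
nonlinearity score in both signs: $\gamma > 1$ mobilizes fast-early
(negative score), $\gamma < 1$ slow-early (positive). Replicate noise is
additive Gaussian with SD equal to `noise_frac` × dusk starch — anchored
to dusk so late-night scatter does not vanish, matching the visible
scatter near dawn in real series — and clipped at zero. The default
`noise_frac = 0.05` is a calibration choice (measured series do not come
with a stated noise model) that makes downstream slope SEs land in a
realistic range; `n_reps = 4` and 2-h sampling mirror the typical
design.

Transcripts are a raised-cosine bump on the log2 scale:
$\text{baseline} + \text{damping} \times A \times g(d)$ with
$g(d) = (1+\cos(\pi d/w))/2$ for circular distance $d < w$, zero beyond.
Clock transcripts have sharp, localized peaks, which a sinusoid cannot
represent with a controllable width; the bump's width $w$ and damping
(for low-amplitude mutant phenotypes) are directly interpretable.
Early-dusk and low-light-day perturbations rescale the generator the way
the carbon budget dictates: a low-light day multiplies $a$ by the
irradiance ratio; an early dusk truncates the light phase, and the
caller chooses whether the night re-paces to anticipated dawn
(compensating, $E$ unchanged) or keeps the baseline rate
(non-compensating, earlier $E$).

What the generator does **not** emulate: the late-night mobilization
slowdown as a separate changepoint (only $\gamma$ bends the night),
sucrose–starch coupling, autocorrelated or heteroscedastic measurement
error beyond the dusk anchoring, and day-to-day biological drift.
Passing recovery tests on this generator therefore demonstrates that the
estimators recover the parameters of their assumed data-generating
process at realistic noise — not that real leaves satisfy that process.

One boundary artifact is worth knowing about. When $E$ coincides exactly
with dawn, the true dawn mean is zero and the zero-clip inflates the
*observed* dawn mean by $\mathbb{E}\max(0, N(0, \sigma))
= \sigma/\sqrt{2\pi}$ (≈ 0.24 µmol at the defaults). The chord of the
nonlinearity score then tilts slightly, biasing the $\gamma = 1$ score a
little below zero (about −0.02 at the default settings) even though the
mean trajectory is perfectly linear. This is a property of the
generator's clipped noise at the zero boundary, not of the score; it
fades when dawn starch is positive, as it is in real wild-type series.

## Determinism, problem sizes, degenerate inputs

Every stochastic routine takes an explicit seed and restores the RNG
state afterwards (`withr::with_seed`); fixed seeds give bit-identical
output, including the full `run_pipeline()` bundle. The test suite and
acceptance script use deliberately moderate problem sizes — 100
generator seeds for exhaustion-time and score recovery, 16 series for
peak-time recovery, 400 simulations for each type-I calibration, 200–
1000 bootstrap draws — chosen so the whole suite runs comfortably on one
CPU while keeping Monte-Carlo error well inside the asserted bands.

Degenerate inputs are refused loudly with typed conditions: too few time
points in a window, zero mean dusk value under normalization, a
non-negative mobilization slope (no projected exhaustion), a rising
night for the score's chord, a lone replicate (SEM reported missing, not
zero), fewer than three shared offsets for profile comparison. A
zero-propagated-error NORM with nonzero distance is reported as infinite
with a warning rather than silently dropped.

## Known limitations

- The nested-fit count depends on the sampling grid; with 4-h sampling
  only one window may exist, making the StEx^app CI unavailable (a
  single root has no spread).
- The peak-time bootstrap assumes at least two replicates per time
  point; designs with singleton time points must be pooled or excluded
  upstream.
- The alignment gridding interpolates mean profiles linearly; strongly
  curved profiles sampled on coarse, incommensurate grids will leak some
  interpolation error into DIST.
- ANCOVA and the two-way alignment ANOVA are fixed-effects OLS on
  replicates, consistent with the analyses they mirror; experiments with
  strong batch structure would need mixed models, which are out of scope
  here.
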