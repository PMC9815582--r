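---
title: "Methods: from raw Hall-sensor voltages to behavior and rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw Hall-sensor voltages to behavior and rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures the package implements, the
assumptions behind them, the tunable parameters and their defaults, what the
simulator does and does not emulate, and the numerical choices that were
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The measurement

A Hall-effect sensor glued to one valve of a giant clam, facing a magnet on
the other valve, reports a voltage (0–5000 mV from a 10-bit ADC on a 5 V
supply) that varies monotonically with valve separation, sampled every 5 s.
The voltage is *not* calibrated to an absolute gape angle: the working point
and gain depend on where sensor and magnet were glued, the sign depends on
magnet orientation, and the baseline drifts slowly (the animals "walk" and
neighboring magnets interfere). Every downstream quantity is therefore built
from within-day standardization rather than absolute voltages.

All timestamps are the deployment's local clock stored with a fixed UTC
offset; the deployment region has no daylight-saving shifts, so calendar
arithmetic ("midnight to midnight") is exact.

## Quality control

Two failure modes dominate this kind of logger. Saltwater intrusion or a
shorted weld pins the output near a supply rail: `detect_rail_fault()` flags
every run of at least 5 minutes at or below 100 mV or at or above 4900 mV.
The thresholds and persistence are configurable; the persistence floor
exists because single-tick excursions are electrical noise, not faults.
Second, a sensor can die quietly, visible as loss of the diurnal cycle:
`detect_diurnal_loss()` computes, over 3-day sliding windows, the fraction
of periodogram power in the 20–28 h band and flags windows below 0.1. That
threshold sits orders of magnitude above the band fraction of white noise
(one Fourier bin in thousands, ~5e-4 for a 3-day window of minute data) and
well below any series with a visible diurnal cycle (typically > 0.3), so the
decision is not delicate. Flags *mask* data — the raw voltages are kept and
excluded from downstream statistics, never repaired — and QC always reads
the raw trace, so it is idempotent.

## Daily normalization

Within each local calendar day with at least 50% valid samples,

$$z_t = \frac{mV_t - \mu_{day}}{SD_{day}}, \qquad
\%closure_t = \frac{z_t - z_{day,\min}}{z_{day,\max} - z_{day,\min}} \times 100.$$

`SD` is the sample (n−1) standard deviation by default (a switch provides
the population version); the choice only rescales z by a factor of order
1/n and cannot change percent closure, which is invariant to any
positive-gain affine transform of that day's voltages. Each complete day
thus has mean-zero, unit-SD z-scores and percent closure spanning exactly
0–100. The cost of the per-day range scaling is fragility on sparse or
constant days, hence the 50% coverage floor and the named-warning drop of
zero-variance days.

Polarity is installation-dependent, so `polarity = "auto"` picks the
orientation under which the dark-hours median exceeds the bright-hours
median — clams close in the dark, and a flipped magnet cannot fake that
ordering without inverting the entire diurnal pattern.

## Light regimes

Hourly mean PAR below 5 µmol photons/m²s defines `dark` ("light virtually
absent"); instantaneous PAR above 100 µmol photons/m²s defines `bright`
(the basking threshold); everything else is `low_light`. Dark takes
precedence at the hourly level, so the three regimes are exhaustive and
exclusive. "Light present" in the median comparison means *not dark*.

## Closure events

Rapid valve claps appear as sudden z-score peaks. A sample is a candidate
iff it is the first-argmax of its centered 3-point window — at a 5-s tick
the window spans more than 15 s, which rejects single-tick noise while
catching closures the animal reverses within ~15 s. Candidate prominence is
the height above the higher of the two flanking minima, each taken between
the peak and the nearest strictly higher sample (or the end of the
contiguous run); candidates below 1.0 daily SD are discarded. The default
of one daily SD is a deliberate choice in the absence of a published
amplitude criterion; it is configurable and `detect_events()` is cheap
enough to sweep. Event boundaries are the nearest outward crossings of
`peak − 0.5 × prominence` (the standard half-prominence width convention;
`reopen_fraction` is configurable because "reopened" admits several
reasonable definitions, and printed event counts are sensitive to it).
Boundaries sit half a grid step beyond the last sample above the level, so
even a single-sample spike has positive duration. Overlapping events merge,
keeping the higher peak, which prevents double-counting a clap with a noisy
summit. Masked or missing spans split the series into independent runs that
events never cross.

The day/night split for event counts uses the nocturnal window
[14:00, 04:00), when the animals sit partially closed and clap most; its
complement is the day window.

## Environmental models

Daily closure counts are joined to daily-mean covariates; fluorescence
channels enter as natural logs floored at the smallest positive observed
value (the floor only protects against detection-limit zeros; the base is a
display choice and a `log10` switch is provided).

`fit_gam()` fits a Gaussian additive model: penalized cubic regression
splines (≤ 9 basis functions) for log chlorophyll-a, log phycoerythrin, pH
and DO, and a linear light term — the indoor light program varies too
little seasonally to support a smooth. Smoothness is selected by REML
rather than GCV: in null calibration at n = 50 the GCV-based term p-values
rejected at 14–20% instead of 5%, while REML-based smooths and the
parametric tests are calibrated. Two tables are reported. The *ANOVA for
parametric effects* — sequential F-tests of each covariate's linear
component, 1 df per term, in the order chlorophyll, phycoerythrin, pH, DO,
light — is the classic layout for this analysis and is exact under a
Gaussian null. The smooth table (edf, F, p from the REML fit) assesses
nonlinear structure beyond the linear components. Counts are pooled across
animals; a per-animal random effect is deliberately out of the default
model because the pooled daily table is what the parametric layout
describes.

`ccf_lagged()` is the classic cross-correlation estimator: covariance at
lag k divided by N and the lag-0 standard deviations, with the
±1.96/√N significance band. **Positive lag means closure frequency lags
the covariate.** This convention is printed in the result because CCF sign
conventions are the classic trap in lagged ecology analyses.

Rank-sum comparisons (dark vs lit closure percentage; day vs night event
durations) report the rank sum of the first-named group alongside the
Mann–Whitney U and the two-sided p from `wilcox.test()`.

## Wavelet rhythms

`cwt_power()` implements the Morlet continuous wavelet transform
(ω₀ = 6) on a log₂-spaced period grid with 20 voices per octave, zero
padding to the next power of two, and power normalized by the series
variance. Significance comes from seeded AR(1) surrogates fitted to the
series: each period's threshold is the (1 − α) quantile of the *pooled*
surrogate null (a thinned sample of in-cone values from every surrogate).
Pooling matters: taking per-surrogate quantiles and averaging them is
biased low for time-correlated wavelet power and roughly doubled the null
exceedance rate in calibration. Cells outside the cone of influence
(e-folding distance √2·s) are never significant. Interior gaps are linearly
interpolated, capped at 20% missing — beyond that, surrogate significance
would be fiction, so the function refuses.

`reconstruct_band()` inverts the transform over a period band with the
standard delta-function reconstruction (C_δ = 0.776 for ω₀ = 6); the series
mean travels with the reconstruction so reconstruction + residual equals
the input exactly. Removing the 18–30 h band and transforming the residual
(`residual_periodicity()`) is how ultradian (6 h, 12 h) structure is
isolated from under the dominant circadian ridge.

`wavelet_coherence()` smooths the scale-normalized cross spectrum and
powers with a boxcar over time (one scale length) and over scale
(±0.6 octave), then forms the squared coherence; without smoothing
coherence is identically 1, and the boxcar widths are the only smoothing
parameters. Phase is the argument of the smoothed cross spectrum;
**positive phase means the first series leads**, so an in-phase pair reads
0 and an anti-phased pair π. Self-coherence is exactly 1 by construction,
which the tests use as an invariant rather than a result.

Problem sizes for the heavy stages are set where the estimates stabilize:
the pipeline's wavelet stage runs on 5-minute averaged percent closure
(the ridge position is unchanged from minute resolution, at a fraction of
the cost) and coherence on the 15-minute grid shared with pH/DO; surrogate
counts default to 100 for standalone analysis and 20–30 inside the
pipeline and validation runs.

## The simulator

`simulate_valvometry()` exists so that every stage can be validated against
known ground truth. Its defaults describe the study system the package was
built around:

* **Light** — an asymmetric solar hump peaking at 09:00 (sharp sunrise
  σ = 1.5 h, slow decline σ = 2.2 h as the sun drops behind obstructions,
  peak ~540) plus a 55 µmol LED square wave from 08:00 to 20:00; the
  combined peak approaches 600 µmol photons/m²s between 08:00 and 10:00,
  total light crosses 100 µmol around 14:00, and hourly means are below 5
  from roughly 20:00 to 04:00. An optional midnight artifact spike mimics a
  known logger firmware quirk; it is off by default and QC deliberately
  does not remove it.
* **Water chemistry** — pH 8.1–8.25 and DO 6.89–9.94 mg/L as clipped
  sinusoids peaking at 20:00, the end of the photoperiod: photosynthesis
  accumulates oxygen and draws down CO₂ through the lit hours and nighttime
  respiration reverses it, so dusk maxima and dawn minima are the expected
  phase in a productive closed tank. This timing also makes nocturnal
  closure *in phase* with pH/DO and anti-phased with light, the qualitative
  pattern the coherence stage is validated against. Temperature is
  25 ± 0.1 °C.
* **Plankton and productivity** — chlorophyll-a is a slowly wandering
  log-baseline plus episodic bloom bursts (half-day rise, 1.5-day die-off,
  ~1 per 12 days); phycoerythrin gets independent bursts. A multi-day
  productivity level (AR(1), 3-day correlation) additionally raises mean
  pH and DO, weakly raises log chlorophyll, and multiplies the clap rate —
  sustained algal activity means both higher pH/DO and more food, so
  closure frequency co-varies with pH at lag zero while the acute bloom
  channel drives the 4-day lagged response.
* **Behavior** — baseline posture follows a logistic function of PAR
  centered at the 100 µmol basking threshold, from 12.7% closed (bright) to
  44.1% closed (dark) pooled, with per-clam gap factors (0.6/1.4/1.0)
  reproducing strong inter-individual spread, a nightly level shift
  (SD 5%), and AR(1) jitter (SD 3%, 1-h correlation). Claps are an
  inhomogeneous Poisson process (0.6/h in the dark, 0.25/h bright,
  per-clam activity factors) whose nightly intensity is multiplied by
  exp(0.8 · z(log chl)) lagged 4 days — the coupling acts on event *rate*,
  not posture, because blooms drive feeding claps, not basking. Durations
  are log-normal with median 40 s and σ chosen so ~90% fall under 100 s;
  clap shape is a 10-s rise to near-full closure, hold, and reopening.
  Sparse long daytime closures model threat responses.
* **Transduction** — offset ~2500 mV, 8 mV per percent closure, 4 mV
  Gaussian noise (quantization-dominated electronics), 2 mV/day linear
  drift plus a slow random walk, optional rail-fault injection, clipping to
  0–5000 mV and integer rounding. The jitter and noise levels were chosen
  so the behavioral noise floor sits below one daily SD, matching the
  plateau-with-discrete-spikes character of real records; with a noisier
  floor, prominence-1 detections are dominated by jitter summits, which
  real records of this system do not show.

One environmental realization is shared by all clams; behavioral draws are
independent per clam apart from the shared drivers. The whole realization
is a deterministic function of the seed, and fixture files are
byte-identical across runs.

What the simulator does **not** emulate: tidal rhythms (the study tank has
none), habituation or any feedback from events to posture, researcher-visit
disturbances as a distinct process (long daytime closures stand in),
heteroscedastic or temperature-dependent sensor noise, and real
deployment-scale inter-individual correlation structure (per-clam gain
variation is a modeling choice, not a reconstruction). Passing the validation suite
therefore shows the pipeline recovers known structure of this kind from
realistic noise — not that real deployments meet these assumptions.

## Numerical and degenerate-input choices

* Empty averaging windows, missing ticks and QC masks are explicit `NA`s;
  nothing is interpolated except immediately before the wavelet transforms,
  where the gap fraction is reported and capped.
* Constant days, zero-variance CCF inputs, empty rank-sum groups, constant
  covariates and rank-deficient model tables raise named errors or named
  warnings identifying the offender; they are never silently skipped.
* Candidate-peak ties (plateaus) break to the earliest index, so a clipped
  full-closure plateau yields exactly one candidate.
* CCF lags are clipped to n − 2 with a warning; a series shorter than three
  times the maximum lag warns that estimates are noisy.
* The additive model refuses tables with fewer than 20 complete days.

## Known limitations

* Percent closure is a within-day *relative* scale; days with little
  behavioral range amplify noise, and cross-day comparisons of absolute
  gape are impossible by design (the instrument is never calibrated to
  millimeters).
* Event durations depend on the reopening convention; counts are robust to
  it, widths less so.
* The parametric-effects ANOVA is sequential, so term order matters in
  collinear tables; the default order is the conventional one for this
  analysis.
* AR(1) surrogates model smooth colored noise; strongly bursty series
  (heavy clap clustering) can exceed the nominal false-positive rate at
  short periods.
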