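# valvometry

Analysis of bivalve valve-gape ("valvometry") records from low-cost
Hall-effect sensor rigs, built for multi-month deployments on giant clams
(*Tridacna*) monitored alongside light, carbonate chemistry, oxygen and
plankton fluorescence. The package takes the raw tab-delimited voltage logs
an Arduino-class logger produces and turns them into quantitative behavior:
how open the animal is, when it claps its valves shut, and how both relate
to the environment on diurnal to multi-week timescales.

A giant clam basks open in the light to feed its photosymbionts, partially
closes at night as a defensive posture, and intermittently claps its valves
to expel pseudofeces while filter feeding. The sensor only reports an
uncalibrated, drifting voltage, so all behavior is extracted through
within-day standardization:

```
z_t        = (mV_t − μ_day) / SD_day
%closure_t = (z_t − z_day,min) / (z_day,max − z_day,min) × 100
```

On top of that the package provides:

* **QC** — rail-fault detection (saltwater intrusion pins the trace near
  0 or 5000 mV) and spectral detection of diurnal-signal loss; flagged
  spans are masked, never repaired.
* **Event delineation** — closure events are prominence-filtered local
  maxima of the daily z-score in a 3-point (>15 s) moving window; an event
  ends when the trace recrosses `peak − 0.5 × prominence`. Daily counts
  are split over the nocturnal window [14:00, 04:00).
* **Light partitioning** — dark (hourly mean PAR < 5 µmol photons/m²s),
  bright (instantaneous PAR > 100), low light otherwise; closure statistics
  and rank-sum comparisons per regime.
* **Environmental models** — a Gaussian additive model of daily closure
  counts (penalized cubic splines for log chlorophyll-a, log phycoerythrin,
  pH, DO; linear light) reported as a classic parametric-effects ANOVA,
  and a lead/lag cross-correlation function where **positive lag means
  closure lags the covariate**.
* **Rhythms** — Morlet continuous wavelet transform with AR(1)-surrogate
  significance, 24-h band reconstruction and residual (ultradian) analysis,
  and wavelet coherence with phase against pH, DO and light.
* **A seeded simulator** — light program, water chemistry, plankton blooms,
  clam behavior and sensor transduction with full ground truth (true event
  times, injected faults, coupling lags), so every stage is testable end to
  end without any deployment data.

## Worked example

Simulate two weeks of three clams, run the pipeline, and look at the
light-partitioned behavior (this is `analysis/01`–`04` condensed; the
numbers below are what the code printed):

```r
library(valvometry)

sim <- simulate_valvometry(sim_config(seed = 42, n_days = 14, n_clams = 3))
res <- run_pipeline(sim$valve, sim$par, sim$env, do_rhythms = FALSE)

res$regime_test
#> dark median 42.8% closure vs 19.6% when light was present
#> (rank-sum W = 1.17e+11, p < 0.001)

daily <- tapply(res$daily$closure_count, res$daily$date, sum)
mean(daily)                        #> 36.6 closures per day, pooled
res$duration_hist$frac_below_100s  #> 0.81

print(res$ccf_chl)
#> <ccf_result> N = 14, ... positive lag = response (y) lags covariate (x)
```

The animals sit far more closed in the dark than under basking light, most
closure events last under 100 s (pseudofeces-expulsion claps), and daily
closure frequency tracks chlorophyll-a with a positive lag of a few days —
on a 60-day run (`analysis/05_envstats.R`) the cross-correlation peaks at
+4 days (r = 0.68 against a 0.25 significance bound), matching the lag the
simulator injects, and the additive model flags pH
(F = 23.1, p = 1.3e-05) while light, phycoerythrin and DO stay
non-significant. The rhythm stage (`analysis/06_rhythms.R`) puts the
wavelet ridge at 24.3 h, finds a 12.1-h residual ridge once the circadian
band is removed, and reads coherence phases at 24 h of −0.56 rad against
pH and DO (in phase) and −3.14 rad against light (anti-phased).

The numbered scripts under `analysis/` run these stages as a workflow,
writing tables under `results/` (`01_simulate.R` writes raw-format fixture
files that `02`–`04` ingest like a real deployment; `05`–`06` model a
60-day realization).

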