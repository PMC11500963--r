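---
title: "Detecting extra-territorial prospecting forays from receiver-array telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting extra-territorial prospecting forays from receiver-array telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many territorial, group-living animals make brief extra-territorial
"prospecting" forays — excursions beyond the home territory thought to
gather information on dispersal opportunities. Forays are fast, cryptic and
rare, which makes them nearly invisible to direct observation. A practical
alternative is a fixed array of radio receivers ("base stations"), one at
each territory centre, that log every pulse of animal-borne transmit-only
tags together with a received signal strength indicator (RSSI). The array
yields millions of detection logs per deployment; `forayr` turns those logs
into station-resolution locations, discrete foray events with duration and
distance metrics, and the behavioural statistics built on them.

```{r setup}
library(forayr)
```

## Station-level localization

Logs for one tag are processed in moving windows of `window_width` seconds
(default 15), advanced in steps of `step` seconds (default 5, the tag pulse
interval). Within a window the mean RSSI per station is computed, and the
window is assigned a "best estimate" location by a deliberately
conservative decision tree:

1. no logs at all: location **unknown** (the tag may be out of range or in
   signal-blocking cover — no spatial inference is drawn);
2. logs from exactly one station: that station;
3. logs from several stations, none the tag's home station: the station
   with the highest mean RSSI;
4. logs from several stations including home: **home** whenever the home
   station's window mean exceeds `home_rssi_threshold`, otherwise the
   station with the highest mean RSSI.

Rule 4 is the *home override*: whenever the home receiver hears the tag at
a strength consistent with the bird being within about 50 m, the bird is
scored as home regardless of other receivers. This sacrifices sensitivity
to short-range movements in exchange for robustness against misclassifying
routine boundary interactions as forays.

Each estimate stands for the `step`-long epoch beginning at its
`epoch_start`; windows overlap, but epochs partition time, so all duration
accounting downstream sums epochs. Two choices here were genuinely open and
are fixed as follows. The window grid is anchored per tag at the first log
time rounded down to a multiple of `step`, so tags are processed
independently. Exact ties in mean RSSI (possible with quantised RSSI
values) are broken in favour of the station of the previous known estimate
— continuity-first, which is conservative against fabricating movement —
and then by smallest station id, which makes output deterministic.

```{r localize-example}
cfg <- analysis_config()
arr <- station_array(
  data.frame(station_id = c("A", "B"), x = c(0, 300), y = c(0, 0)),
  home_of = c(bird1 = "A")
)
logs <- data.frame(
  tag_id = "bird1", station_id = c("A", "A", "B", "B", "A"),
  time = c(0, 5, 40, 45, 90), rssi = c(-2, -3, -25, -24, -4)
)
localize_tag(logs, arr, "bird1", cfg)
```

## Foray detection

The epoch series is segmented into candidate non-home *runs*: a run opens
at a known non-home epoch and closes at the next known **home** epoch.
Unknown epochs never break a run — an animal far outside the array
routinely goes undetected mid-foray, and requiring continuous coverage
would discard exactly the longest excursions. A run qualifies as a foray
iff

* its known non-home time exceeds `min_nonhome_time` (default 15 s,
  strictly; with 5-s epochs that means at least 4 known non-home epochs),
  and
* the furthest assigned station lies more than `distance_threshold`
  (default 250 m) from the home station, strictly.

With receivers at territory centres spaced roughly 94 m apart, a 250-m
threshold means the bird's nearest receiver was beyond its neighbours'
territory centres, which makes ordinary boundary disputes essentially
impossible to misread as forays, at the cost of missing short-range
prospecting. Foray *duration* runs from the first non-home estimate to the
first subsequent home estimate; foray *distance* is the straight-line
distance from home to the furthest assigned station, and the round-trip
estimate is twice that — a lower bound, since real paths are not straight
and the furthest station understates the furthest position.

Runs still open at the end of the data, and runs that begin before the
animal was ever scored home, carry `censored = TRUE`. They are emitted (so
nothing is silently discarded) but excluded from rate summaries by default,
because their durations are not observed; including them would mean
fabricating end points. A foray is counted on the civil day containing its
start (days switch at local midnight; `tz_offset_hours` shifts log times
into local time first, and the bundled simulator emits times that are
already local, so its offset is 0).

## Calibration

The home override needs an RSSI threshold meaning "within about 50 m".
`fit_rssi_distance()` estimates it from calibration-transect data (tags
held at known distances from receivers) with the standard log-distance
path-loss model, `rssi = a + b log10(d)`, fitted by least squares and
evaluated at the 50-m reference. Log-distance decay is the textbook radio
propagation model and matches the curvature of field calibrations; the
residual SD quantifies the (considerable) scatter from vegetation, tag
orientation and height, which is why the threshold feeds a conservative
override rather than a distance estimator. An `empirical-mean` mode simply
averages observations near the reference distance instead, for users who
prefer not to impose a functional form. Calibration records of
sent/received pulse counts yield an empirical detection-probability curve
(`detection_probability_curve()`), optionally smoothed by decreasing
isotonic regression.

The packaged default threshold is −11.484, the value derived for the
deployment this workflow was built around; any recalibrated value can be
passed through `analysis_config(home_rssi_threshold = )`.

## The synthetic deployment generator

Every stage is validated against simulated deployments with known ground
truth (`sim_config()`, `make_array()`, `simulate_movement()`,
`simulate_logs()`). The generator's defaults emulate the deployment scale
the pipeline targets:

* 35 stations on a jittered grid with mean nearest-neighbour spacing about
  93.7 m (5% positional jitter keeps the realised spacing within the 10%
  contract while breaking the exact lattice);
* 27 birds (13 males, 14 females) tracked 37 days, tags pulsing every 5 s;
* forays as a per-bird Poisson process — 0.8/day for females, 1.4/day for
  males (ratio 1.75; population mean 1.09 forays/day);
* log-normal foray durations with median 5.67 min and log-SD 1.54 (mean
  18.6 min), and log-normal one-way distances with median 324 m and log-SD
  0.46 (so the median round trip is about 648 m);
* straight-line travel at 5 m/s to a target point in a uniform random
  direction, a dwell, and return; positional jitter of 5 m (SD) around the
  modelled path;
* RSSI = 30.99 − 25 log10(d) + N(0, 4) — the intercept places the mean
  RSSI at 50 m at the deployed −11.484 threshold — and logistic detection
  `plogis((70 − d)/15)`, which reproduces a realistic log volume of
  roughly 1–3 logs per pulse for a bird at home.

Where the emulated deployment reports a value (station count, spacing,
tracking length, pulse rate, rate/duration/distance scales), the default is
that value; the remaining constants (speed, jitter, detection range, noise
SD) are fixed once at field-realistic magnitudes and are not tuned.

The generator deliberately omits several features of real data: territory
boundaries and social interactions (birds are points at territory centres),
anisotropic propagation and terrain, diel activity rhythms (foray times are
uniform), tag failure, and bird-level rate heterogeneity beyond sex.
Passing tests therefore demonstrate that the pipeline recovers what it
claims *under the stated movement and propagation model* — not that any
field deployment meets those assumptions.

## Validation design

The test suite checks, among other properties:

* **Oracle equivalence.** The vectorized windowing/decision-tree and the
  run-scan segmentation match naive brute-force re-implementations on 200
  random instances of up to 5,000 epochs.
* **Monotonicity.** Foray counts are non-increasing in both the distance
  threshold (200–350 m) and the minimum non-home time.
* **Perfect recovery in the noise-free regime.** With noiseless RSSI,
  step-function detection and every true foray aimed at a station more
  than twice the distance threshold from home, detection achieves recall
  and precision of exactly 1.
* **End-to-end ratio recovery.** The full
  simulate → localize → detect → rates chain is replicated at three fixed
  seeds at the default scale (27 birds × 37 days); the mean estimated
  male:female log rate ratio must lie within two Monte-Carlo standard
  errors (between-replicate SD/√3) of the generating log 1.75. The
  between-replicate SE is used deliberately: per-bird foray detectability
  depends on where a bird's home sits in the array, a between-deployment
  noise source that the within-deployment model SE cannot capture, and one
  that makes single-replicate checks of a stochastic pipeline
  anticonservative.
* **Trade-off recovery.** The provisioning trade-off model recovers a
  generating slope of −0.3 within 3 SE at n = 200 watches, with a negative
  sign in at least 90% of 200 seeded replicates.

## The prospecting–provisioning trade-off

For cooperative breeders, the behavioural question is whether prospecting
trades off against helping. `trailing_rate()` computes each bird's foray
rate over the `w` civil days preceding (and excluding) a provisioning
watch — "preceding" reads as the half-open window `[day − w, day)`.
`build_tradeoff_table()` pairs watches with that covariate, dropping
watches whose window extends before the bird's tracking deployment rather
than computing a rate from partial exposure. `fit_tradeoff_model()` then
fits a Poisson mixed model of feed counts with log watch-hours as offset
(so the response is effectively feeds/hour), fixed effects for the trailing
rate, sex and brood covariates, and a bird-level random intercept (plus
group when present), via `lme4::glmer()`. `window_sensitivity()` re-fits
over a range of window lengths, since any particular `w` is somewhat
arbitrary. The exact binomial sex test (`exact_binomial_sex_test()`) uses
the conventional two-sided "minlike" definition — the sum of probabilities
of outcomes no more likely than the one observed — with one-sided
alternatives available.

```{r tradeoff-example}
scfg <- sim_config()
counts <- simulate_daily_counts(scfg, seed = 8, n_males = 10,
                                n_females = 10, days = 30)
obs <- simulate_provisioning(counts, scfg, seed = 8, n_obs_per_bird = 10)
tab <- data.frame(bird_id = obs$bird_id, sex = obs$sex, date = obs$date,
                  provisioning_hours = obs$hours, feeds = obs$feeds,
                  trailing_prospecting_rate = obs$true_trailing_rate,
                  window_days = 3L, brood_size = obs$brood_size,
                  brood_age = obs$brood_age)
fit_tradeoff_model(tab)
```

## Numerical and degenerate-input conventions

* All inequalities in the foray criteria and the home override are strict,
  matching the definitions above.
* Empty inputs (no logs, no forays, empty provisioning tables) return
  empty, correctly-typed tables rather than errors.
* Malformed log rows are dropped with a reported count by default; a
  `strict` flag escalates them, since field logger dumps are dirty and a
  hard failure on row one helps no-one.
* Calibration requires at least three distinct positive distances; a
  non-negative fitted slope triggers a validity warning rather than an
  error, because a flat fit can still be a usable empirical threshold.
* Simulation randomness flows from one master seed through fixed per-stage,
  per-bird substreams, so any stage or any single bird can be re-run in
  isolation with identical results.

## Known limitations

Location granularity is the station: there is no multilateration, so foray
distances are lower bounds quantised to the array geometry, and forays
whose furthest point falls between distant stations can be missed entirely.
Detection of a given foray depends on where the bird's home sits in the
array — edge birds' outward forays leave the covered area quickly — so
absolute foray rates from a finite array underestimate true rates, and
analyses should (as here) rely on contrasts that are not confounded with
array position. Censored-run handling discards genuinely long excursions
cut off by the deployment end, slightly biasing duration summaries
downward. The trade-off model is a fitting contract on the pipeline-built
covariate table; it does not address zero-inflation or overdispersion
beyond the bird-level intercept.
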