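---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery in `noctshift`: the
response statistic, the covariates, the inference chain, the synthetic
study generator, and the numerical and design decisions behind each.

## The nocturnality response

Each independent detection event receives a continuous response: the
circular 24-hour distance, in decimal hours, between its timestamp and the
solar noon of the same calendar date,

$$N = \min(|\Delta|,\; 24 - |\Delta|) \in [0, 12],$$

where $\Delta$ is the signed clock difference in hours. $N=0$ is solar
noon, $N=12$ solar midnight. Working on the circle (rather than taking a
raw same-day difference) guarantees the $[0,12]$ codomain even when solar
noon falls far from clock noon. The reference transit is the event's own
calendar date; using the nearest transit instead would change values by at
most the day-to-day drift of solar noon (under a minute).

Solar noon comes from the NOAA solar-position formulation: the equation of
time from the fractional-year expansion, a longitude correction of 4
minutes per degree, and the fixed study UTC offset, with one refinement
pass evaluating the fractional year at the transit itself. Against an
independent ephemeris formulation (sidereal-time/hour-angle root finding)
the result is accurate to well under a minute across 1950–2100 — three
orders of magnitude below the response's scale. Timestamps carry one fixed
UTC offset for the whole study; daylight-saving transitions are
deliberately not modeled, which keeps results reproducible from the files
alone. Solar noon is evaluated per station (station longitudes are
available and stations may span several minutes of transit time); a single
reference point can be emulated by passing constant coordinates.

The lunar illuminated fraction uses the standard low-precision ecliptic
series for the moon's phase angle $i$ (elongation, solar and lunar mean
anomalies) with $k = (1 + \cos i)/2$, accurate to about 0.002 — far inside
the 0.02 tolerance that matters for a 0–1 covariate.

## Detection events

Within each station × species stream, a record starts a new event iff its
gap to the *immediately preceding* record strictly exceeds the threshold
(30 min wildlife, 1 min humans). Two choices deserve note:

* **Chain rule.** The gap is measured from the previous record, not from
  the event's first record; this matches standard camera-trap practice.
  The event-start anchor is available via `anchor = "event_start"` for
  sensitivity analysis.
* **Strict inequality.** A gap of exactly 30:00 does *not* open a new
  event ("more than 30 minutes").

Humans are one undifferentiated class. Event counts are conserved across
partitioning into days, ISO-8601 weeks (Monday–Sunday) and calendar
months; weeks and months are calendar conventions chosen for
reproducibility, since rates must divide human counts by *active*
camera-days in the same period. A period with zero active days yields a
missing rate — a camera that was off is not evidence of zero human use —
and such events are dropped from the model table with an accounting
message.

## Geometry

All geometry is exact and planar: line density is total polyline length
clipped to the closed 500 m disk (segment–circle intersection solved per
segment) divided by $\pi r^2$; boundary distance is the minimum
point-to-segment distance. Geographic inputs are first projected with a
local equirectangular transform anchored at the stations' centroid — over
a ~10 km extent the projection distortion is on the order of 0.1%, well
inside the 1% reproducibility tolerance asserted in the tests. Crown
closure is consumed as a supplied per-station point attribute (it
characterizes light availability at the camera, not in a buffer).

## Inference

Predictors are z-scaled (mean 0, SD 1) on each species' final analysis
table, after row drops, and screened pairwise for |Pearson r| ≥ 0.7.

**Flat-prior linear model.** With an improper uniform prior on the
coefficients and the reference prior $1/\sigma^2$, the marginal posterior
of $\beta$ is multivariate Student-t centered on the least-squares
estimate with $n-p$ degrees of freedom and scale $s^2 (X'X)^{-1}$. The
analytic path evaluates this closed form; it is exact, deterministic, and
equals the least-squares solution in its posterior mean (asserted against
an independent normal-equations oracle on every fit in the test suite).
The sampling path is a conjugate Gibbs sampler — $\beta\,|\,\sigma^2$
normal, $\sigma^2\,|\,\beta$ inverse-gamma — run with 4 chains × 100,000
iterations, burn-in 5,000, thinning 1 by default, with the classic
Gelman–Rubin $\hat R$ per parameter and the < 1.1 convergence bar. Both
paths agree to Monte-Carlo error; the sampler exists to mirror an MCMC
workflow and to exercise convergence diagnostics, and its defaults are the
analysis constants, scaled down explicitly in tests.

**Credible intervals and evidence.** Intervals are equal-tailed (for the
symmetric Student-t marginals they coincide with highest-density
intervals, and equal-tailed quantiles are directly testable). A
coefficient has *strong* evidence when its 95% interval excludes zero,
*moderate* when only its 90% interval does. A 90% equal-tailed interval
excluding zero implies the posterior probability of the coefficient's sign
is at least 0.95 (a one-sided 95% interval) — an identity of the t
marginal that the suite checks across a thousand random fits. Tiers
express strength of *evidence* and are reported alongside, never instead
of, effect sizes.

**Bayes factors.** With improper flat priors the marginal likelihood is
undefined, so model evidence is approximated by the Schwarz/BIC criterion:
$BF = \exp((BIC_0 - BIC_1)/2)$ with the Gaussian log-likelihood at the
least-squares fit. This preserves the decision rule (select the human
measure with the largest BF, include it only if BF > 1, tie-break
daily > weekly > monthly) while being fully reproducible. The numeric BF
values of any particular MCMC tool are tool-internal and are not targeted.
The preliminary scale models are univariate (response against one human
measure), which means the scale analysis measures *total* explanatory
value: when station-level confounders (e.g. trail density) correlate
positively with both human use and nocturnality, part of their signal
loads onto the human measure that best proxies station-level exposure —
the least noisy one. This is a property of the published design worth
keeping in mind when interpreting selected scales.

## Spatial diagnostics

Moran's I over per-station values (the per-species mean nocturnality by
default),

$$I = \frac{n}{W}\,\frac{\sum_{ij} w_{ij} (x_i-\bar x)(x_j-\bar x)}
{\sum_i (x_i-\bar x)^2},$$

with inverse-distance, row-standardized weights by default (k-nearest
available). The analysis does not prescribe a weight scheme, so the scheme
is recorded in every output. The p-value is a two-sided permutation test:
the rank of $|I - E[I]|$, $E[I] = -1/(n-1)$, among label permutations,
with $(1 + \#exceed)/(B+1)$. Under a spatially random null the test
rejects at the nominal 5% rate (checked over 200 seeded replicates); the
statistic is invariant to location and positive scaling of the values.

## Activity curves

Diel densities use von Mises kernels on the 24 h circle
($\theta = 2\pi t/24$). The automatic concentration is the
maximum-likelihood-based plug-in standard in activity-overlap analysis:
$\hat\kappa$ solves $A_1(\kappa) = \bar R$, then
$\kappa_{bw} = \left(\frac{3 n \hat\kappa^2 I_2(2\hat\kappa)}
{4\sqrt{\pi} I_0(\hat\kappa)^2}\right)^{2/5}$.
Densities are evaluated on a 512-point grid over $[0,24)$, integrate to
1 (periodic trapezoid; asserted to $10^{-6}$), and are reported in clock
time — the axis on which human diurnality is defined — with solar-anchored
curves available by transforming the input times. Degenerate samples
(all events at one instant) are capped at the concentration a 512-point
grid still resolves.

## The synthetic study generator

The generator's defaults are the study conditions, fixed once:

* **Design**: 58 stations ≥ 1 m apart in a 10 km × 10 km planar landscape
  anchored at 49.4°N, −122.5°E (UTC−8), March 2019 – September 2020.
* **Effort**: each camera-day independently inactive with probability
  0.29, giving ≈ 23,900 active camera-days.
* **Geometry**: random-walk trail (40) and road (10) polylines and a
  jittered southern boundary; station covariates are *computed from* these
  layers, so the emitted tables are reproducible from the emitted
  geometries by construction (and survive the GeoJSON round trip within
  1%). Crown closure is Beta(6, 3).
* **Human traffic**: Poisson counts per active camera-day with log-mean
  combining a standardized trail-density effect (0.6), a station-level
  popularity term (SD 0.8) and a station-week fluctuation (SD 0.5), each
  mean-calibrated so the average station sees 4.7 detections/camera-day
  (≈ 111,000 detections study-wide). Without the two heterogeneity terms
  the three temporal measures of human presence collapse into near-perfect
  mutual correlation (r ≈ 0.99) and correlate with trail density at
  r ≈ 0.85–0.9; with them the generator reproduces the regime the analysis
  expects of field data — the human measures flag each other in the
  collinearity screen (r ≈ 0.87–0.96) while no other pair reaches 0.7.
  87.8% of detection times fall in 09:00–18:00, uniform within and outside
  the window (the simplest shape meeting that constraint).
* **Wildlife**: per species, Poisson event counts per station (six focal
  species with diel intercepts 4.70–9.23 decimal hours and study-wide
  totals ≈ 1,900 events); per event, nocturnality drawn as
  $\beta_0 + \sum_k \beta_k z_k + \varepsilon$ on the standardized
  covariate scale with $\sigma = 2$, default slopes
  (0.35, 0.81, −0.87, −0.29, 0.27, 0.27) matching the magnitudes the
  analysis is meant to resolve. The human coefficient acts through the
  monthly detection rate by default — the dominant scale in this study
  system, and (see the Bayes-factor note above) the scale a univariate
  screen can cleanly re-identify.
* **Placement**: out-of-range draws are *reflected* at 0 and 12 (a defined,
  testable mapping whose bias stays small at $\sigma \le 2.5$); the event
  is stamped at the drawn circular distance from its date's solar noon,
  before/after noon by fair coin — the statistic is side-blind — flipped
  only when a side would leave the calendar date, so that recomputing
  nocturnality from the timestamp reproduces the drawn value to a second.
  Same-station events are spaced > 30 min (dates are redrawn for the rare
  collisions, keeping each event's residual), so independence filtering
  preserves event counts exactly.

Covariates, coefficients, residual SD and drawn responses are returned as
ground truth. Recovery tests at ~2,000 events show posterior means within
±0.15 of the true standardized slopes for ≈ 97% of coefficients; the
residual discrepancy is reflection attenuation, which is largest for the
strongest slopes.

**What the generator does not emulate**: image-level processes (blanks,
vehicles, classification error), detection-probability differences among
cameras, seasonal or weather-driven diel shifts, species interactions, and
any non-linear covariate response. The per-species Poisson event-count law
is a stand-in, not a claim about the study system. Passing recovery tests
therefore demonstrate that the inference chain is correct and calibrated
for data generated under its own assumptions — not that field data meet
those assumptions.

## Problem sizes in the test suite

The suite's simulation-based checks use: 1,000 random fits for the
CI/sign identity; 100 random designs for the least-squares oracle; 1,000
random streams for the event-filter oracle; 500 replicates at n = 500 for
interval calibration; 100 replicates of the 58-station, ~2,000-event
recovery scenario; 200 replicates for the Moran null; and 10⁶ random
timestamps for the nocturnality bound. These sizes give binomial/Monte
Carlo noise comfortably inside each asserted band.
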