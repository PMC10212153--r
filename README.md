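# noctshift

Camera-trap analysis of how direct human presence and land-use
infrastructure shift mammalian diel activity toward nocturnality.

`noctshift` is for wildlife ecologists working with motion-triggered camera
grids. It takes raw timestamped detection records (wildlife and humans),
camera effort logs, station attributes and trail/road/boundary line
geometries, and carries them through a complete, reproducible inference
chain:

1. **Detection events.** Raw records are collapsed into independent
   detection events: a record starts a new event when its gap to the
   previous record of the same station and species strictly exceeds a
   threshold (30 min for wildlife, 1 min for humans).
2. **Nocturnality.** Each event gets a continuous response
   `N = min(|Δ|, 24 − |Δ|)` — the circular distance in decimal hours
   between the event timestamp and that date's solar noon, computed from
   the NOAA solar-position equations. `N = 0` at solar noon, `N = 12` at
   solar midnight; an event 1 h 30 min either side of solar noon scores
   1.50.
3. **Covariates.** Direct human presence at three temporal scales (daily
   count; weekly and monthly detections per active camera-day), trail and
   road density in a 500 m buffer (exact segment–circle clipping, m/m²),
   distance to the urban-wildland boundary, lunar illuminated fraction, and
   crown closure.
4. **Inference.** Predictors are z-scaled and screened for collinearity
   (Pearson |r| ≥ 0.7). Because the three human measures are mutually
   collinear, one is chosen per species by comparing univariate models
   against an intercept-only null with BIC-approximated Bayes factors
   (`BF = exp((BIC₀ − BIC₁)/2)`, kept only if `BF > 1`). The final model is
   Bayesian linear regression under flat coefficient priors and the 1/σ²
   variance prior, so the coefficient posterior is the exact multivariate
   Student-t centered on the least-squares solution; a conjugate Gibbs
   sampler (4 chains × 100,000 iterations, burn-in 5,000, thinning 1,
   Gelman–Rubin R-hat < 1.1) is available to mirror an MCMC workflow.
   Effects are tiered: **strong** evidence if the 95% credible interval
   excludes zero, **moderate** if only the 90% interval does.
5. **Diagnostics.** Moran's I permutation tests for spatial autocorrelation
   of per-station mean nocturnality, and von Mises circular kernel
   densities of diel activity.

A synthetic-study generator (`sim_config()`, `simulate_study()`) emulates a
58-station, 18-month study — diurnally concentrated human traffic, species
with distinct diel baselines, linear covariate effects on nocturnality —
and returns the ground truth needed for parameter-recovery and calibration
testing.

## Worked example

```r
library(noctshift)

# the nocturnality statistic
ctx <- solar_ctx(latitude = 49.4, longitude = -122.5, utc_offset_hours = -8)
noon <- solar_noon(as.Date("2019-06-15"), ctx)
noon
#> [1] "2019-06-15 12:10:01 UTC"      # local clock time of solar transit
nocturnality(noon - 90 * 60, ctx)
#> [1] 1.5                            # 1 h 30 min before solar noon
nocturnality(noon - 12 * 3600, ctx)
#> [1] 12                             # solar midnight, the maximum

# a full synthetic study and analysis
res <- run_pipeline(pipeline_config(simulate = sim_config(), seed = 5))
report_tables(res)$detections
#>             species n_events mean_nocturnality min_nocturnality max_nocturnality
#> 1        black_bear      284              4.92           0.1156             11.8
#> 2 black_tailed_deer      717              5.74           0.0433             11.8
#> 3            bobcat      215              8.08           0.5496             11.9
#> 4            cougar       45              6.87           0.6588             11.7
#> 5            coyote      416              7.13           0.0412             11.9
#> 6     snowshoe_hare      250              8.95           1.1522             12.0
```

`n_events` counts independent 30-minute events per species;
`mean_nocturnality` is the species' average distance from solar noon in
decimal hours (larger = more nocturnal), and the min/max columns show each
species' diel range. `report_tables(res)` also returns the per-species
Bayes factors with the chosen temporal scale, the coefficient estimates
with 90/95% credible intervals and evidence tiers, and the Moran's I
diagnostics. The same stages are scriptable from a shell via
`inst/cli/noctshift.R` (`simulate`, `events`, `covariates`, `scale-select`,
`fit`, `diagnose`, `activity`, `report`).

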