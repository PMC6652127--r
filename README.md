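# rehabsense

Wearable-sensor analytics for subacute rehabilitation cohorts: from raw
wrist-accelerometer and BLE-beacon streams to the group statistics and
cross-validated outcome models that ask *which baseline activity and
location features separate patients re-admitted to hospital from patients
who return to the community*.

Patients wear a smartwatch from 9 am to 6 pm. The watch samples triaxial
acceleration at 16 Hz (±2 g, gravity included) and overhears BLE beacons
mounted at locations of interest in the resident and therapy rooms
(advertising every 250 ms). `rehabsense` implements the full chain:

1. **Signal processing** — per-sample signal magnitude
   `SM = sqrt(ax² + ay² + az²)`, conversion at 1 g = 9.81 m/s², 10-s
   windows of 160 samples with 1-s overlap, a zero-phase 5th-order
   Butterworth band-pass (0.5–8 Hz) applied per batch, and the per-window
   mean absolute deviation `MAD = (1/n) Σ|xᵢ − x̄|` as the activity-energy
   proxy. Windows are **active** iff MAD ≥ 0.02 m/s² (a constant 0.02 m/s²
   from rest moves the wrist `½·a·t² = 1 m` in 10 s).
2. **Activity recognition** — 7 window features (moments + spectral peak)
   feeding a three-stage hierarchy: walking vs stationary (learned),
   active vs idle (the MAD threshold), stand/sit/lay (learned).
3. **Indoor localization** — RSSI clipped into [−100, −50] dBm, per-window
   per-beacon medians, nearest-beacon assignment, and aggregation of
   sublocations (shower/toilet/sink → bathroom, …) into rooms.
4. **Feature engineering** — inclusion rules (≥ 4 h wear and ≥ 15 min
   therapy-room wear within the first 3 days; earliest qualifying day is
   baseline) and the normalized taxonomy: time %, energy intensity
   (energy ÷ minutes in the same state/location) and energy % per activity
   state and location.
5. **Cohort statistics** — Kruskal–Wallis and chi-square comparisons,
   Cohen's `d = (m₁ − m₂)/√((s₁² + s₂²)/2)` (average-variance pooling),
   Spearman correlations, and stratified 3-fold cross-validated shallow
   random forests (max depth 2, random state 40, balanced class weights,
   hospital as positive class).
6. **Synthetic cohort generator** — protocol-faithful simulation (wear
   dropout, daily ~1 h therapy block, posture-dependent gravity, walking
   oscillation at 1.5–2.5 Hz, log-distance path-loss RSSI anchored at
   −66 dBm @ 1 ft) with programmable between-group effects, so every stage
   is testable without clinical data.

## Worked example

```r
library(rehabsense)

# the published effect-size convention, from printed group summaries
round(cohensD(44.22, 7.94, 32.68, 7.30), 2)
#> [1] 1.51

# the kinematic gloss of the active/idle threshold
displacementFromAcceleration(0.02, 10)
#> [1] 1

# a small synthetic cohort, end to end under one seed
cfg <- pipelineConfig(seed = 40, nCommunity = 3, nHospital = 2, days = 2)
res <- runPipeline(cfg)
res$provenance$included
#> [1] 5
head(res$stats[, c("feature", "mean_C", "mean_H", "p", "d")], 5)
#>        feature mean_C mean_H      p    d
#> 1  e_loc_chair 688.55 313.63 0.0833 2.99
#> 2 ei_loc_chair   8.77   4.17 0.0833 2.66
#> 3    ei_active  44.09  27.85 0.0833 2.08
#> 4    e_walking 246.28  75.76 0.0833 1.91
#> 5 epct_walking   3.89   1.25 0.0833 1.71
```

`runPipeline()` simulates the cohort, processes and localizes every
window, trains the activity hierarchy on ground-truth labels, applies the
inclusion rules, and ranks each feature by Kruskal–Wallis p (ties by |d|).
`mean_C`/`mean_H` are the community/hospital group means of each feature;
with only 5 patients the p-values are floor-limited — at realistic sizes
(145 vs 9) the programmed resident-room intensity contrast (d = 1.25) is
recovered, which the test suite checks over 200 replicate cohorts. Passing
an output directory (`runPipeline(cfg, "out")`) writes `features.csv`,
`stats.csv`, `model.csv`, the config and a provenance log; identical seeds
reproduce identical files. A thin CLI (`inst/scripts/rehabsense-cli.R`)
exposes `simulate` and `run-all`.

## Layout

```
R/                    S4 classes (AccelStream, BeaconStream, BeaconLayout,
                      ProtocolSchedule, CohortConfig, FilterSpec,
                      HierarchicalModel, SensorCohort) and the module
                      functions
tests/testthat/       unit, property and acceptance suites
scripts/acceptance.R  headline-quantity recomputation
vignettes/            methods vignette (model, parameters, design choices)
inst/scripts/         command-line wrapper
```
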