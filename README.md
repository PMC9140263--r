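# cetatrack

Satellite-track reconstruction, behavioural segmentation and migration
bioenergetics for single-animal cetacean telemetry.

`cetatrack` implements the complete analysis chain used to turn raw Argos
satellite fixes from a migrating whale into a migration phenology and an
energy budget:

1. **Pre-filtering** — speed/distance/angle filtering of raw Argos fixes
   (max plausible speed 9 m/s, class-Z removal), on WGS84 geodesics.
2. **Track reconstruction** — a continuous-time correlated random walk
   (integrated Ornstein–Uhlenbeck velocity) state-space model observed
   through each fix's Argos error ellipse, fitted by maximum likelihood
   (Kalman filter in compiled code) and smoothed to regular 6-hourly
   positions with uncertainty.
3. **Movement persistence** — a time-varying persistence index
   γ ∈ (0, 1) (0 = area-restricted search, 1 = directed transit)
   estimated from the regular displacements with a logit random-walk
   prior and Laplace-approximated marginal likelihood.
4. **Segmentation** — exact dynamic-programming penalized-contrast
   (Lavielle) change-point detection on γ to date migration phases, and
   a two-segment split of the southbound speed series to date calving.
5. **Current correction** — nearest-in-time-and-space surface currents
   subtracted from over-ground velocities to obtain swim speeds through
   water, with along-track support / cross-flow decomposition and a
   resting (≤ 0.5 m/s) vs transiting classification.
6. **Bioenergetics** — Kleiber basal maintenance
   `BMR = 70 · M^0.75` kcal/day and drag-based cost of transport
   `P = λ/(2 ε_A ε_P) · ρ S C_d V³` (W), accumulated per 6-h step into
   migration-window budgets and theoretical slower-speed scenarios.
7. **Routes** — least-cost paths through water (Dijkstra on a
   16-connected water-cell graph, geodesic edge weights, depth > 10 m)
   to compare the travelled route against the shortest possible one.
8. **Synthetic deployments** — a generator with known ground truth
   (phase plan, calving event, Argos error model, toy current and depth
   grids) so the full chain is testable end to end without any data
   download.

It is aimed at movement ecologists who want a self-contained, tested
version of this workflow (the field's standard tooling spreads it over
`trip`, `foieGras`/`aniMotum`, `adehabitatLT`, `marmap` and custom
scripts, several of which are archived or hard to install together).

## Worked example

Simulate a paper-scale deployment (321 days, Norway → Iceland → West
Indies → Barents Sea, calving en route) and push it through the whole
pipeline:

```r
library(cetatrack)

spec  <- paper_like_scenario(seed = 42)
truth <- simulate_truth(spec)
obs   <- observe_argos(truth, spec)       # ~4,200 irregular Argos fixes
cur   <- make_current_field(spec, truth)

res <- run_pipeline(obs, run_config(seed = 42), currents = cur,
                    out_dir = "whale_run")
res$budget
#> Migration energy budget
#>   duration           169.8 days (transiting 141, stationary 29)
#>   distance           18766 km
#>   median speed        1.45 m/s (IQR 0.55)
#>   E_COT              23349 MJ
#>   maintenance       113405 MJ
#>   E_total           136754 MJ   (806 MJ/day)
```

The budget covers the detected migration window (departure from the
winter feeding fjords to arrival south of the summer feeding grounds):
~170 days, ~18,800 km at a median swim speed of ~1.4 m/s. Maintenance
(Kleiber BMR for a 30-tonne female, 668 MJ/day) dominates the total;
the cubic drag law puts the swimming cost near 23,000 MJ. The pipeline
recovers the seven behavioural segments of the generating plan
(`res$phases`), and dates the calving change-point on the southbound
leg within a day of the truth — a drop in median swim speed from
1.71 to 1.39 m/s on March 24 (`res$calving`). Per-step outputs are in
`res$track`; everything is also written to `whale_run/` as CSV/GeoJSON
with a hash manifest.

Desk-level energetics work without any simulation:

```r
bmr_daily(bioenergetic_params())          # 668.07 MJ/day at 30 t
scenario_sweep(9000, c(1.1, 0.9), reference_days = 71)
#>   speed duration_days delay_days  e_cot_mj maintenance_mj e_total_mj
#> 1   1.1      94.69697   23.69697  5177.711       63264.09   68441.80
#> 2   0.9     115.74074   44.74074  3466.071       77322.78   80788.85
```

— migrating the 9,000 km northward leg at 1.1 (0.9) m/s instead of the
observed pace would delay arrival by ~24 (~45) days and trade transport
cost against maintenance.

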