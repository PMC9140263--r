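---
title: "Models and methods behind cetatrack"
author: "cetatrack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cetatrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cetatrack` turns raw Argos fixes from a single migrating whale into a
dated migration phenology and an energy budget. This vignette documents
the statistical models, every tunable that matters, the numerical
choices, what the synthetic-data generator does and does not emulate,
and the package's known limitations. The worked example lives in the
README; nothing here states a result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Pre-filtering raw fixes

Argos positions carry occasional gross outliers. `sda_filter()` removes,
in order: (i) all fixes of quality class Z (invalid by definition);
(ii) fixes whose transit speed both from the previous and to the next
retained fix exceeds `vmax` (default 9 m/s, far above any sustained
cetacean speed), removed one per pass so the result is independent of
scan order; (iii) "spikes" — out-and-back excursions with an internal
angle below 15° (25°) and both legs longer than 2.5 km (5 km). All
speeds and leg lengths use WGS84 geodesics rather than projected
distances, so the filter behaves identically at 70°N and at 20°N. Ties
among equally implicated fixes are resolved by worse quality class,
then by later time, making the output deterministic. Removing Z-class
rows *before* the speed criterion is a package choice (the order is
observationally equivalent for the retained set but changes which rows
the report attributes to which rule).

The working planar frame is an azimuthal equidistant projection,
centered by default at 20°W 45°N (mid North Atlantic), built from
geodesic primitives: a point maps to (d·sin α, d·cos α) with d and α
the geodesic distance and forward azimuth from the center. Distance and
azimuth *from the center* are exact by construction; distances between
two off-center points are distorted (up to ~10% at 5,000 km from the
center), which is why speeds are always recomputed on geodesics.

## Track reconstruction (CTCRW state-space model)

The movement model is a continuous-time correlated random walk:
velocity is a 2-D Ornstein–Uhlenbeck process,
`dv = −β v dt + σ dW`, and position integrates velocity. Between
irregular fix times the model is discretised *exactly*, so no
interpolation error enters the likelihood. Each fix is observed through
a 2-D Gaussian whose covariance comes from its Argos error ellipse:
variance `semi_major²` along the major axis, `semi_minor²` along the
minor axis, rotated by the orientation measured clockwise from north.
Fixes without an ellipse (common for classes A/B in older exports) fall
back to class-based isotropic SDs (3: 250 m, 2: 500 m, 1: 1,500 m,
0: 4,000 m, A: 6,000 m, B: 10,000 m; configurable). A single inflation
factor ψ on all observation covariances is estimated by default.

The likelihood is evaluated by a Kalman filter in compiled code and
maximised by Nelder–Mead from three spread starting values (velocity
autocorrelation time scales of 1 h, 6 h, 24 h); the best likelihood
wins, making the fit deterministic without random restarts. Regular
6-hourly states (position, uncertainty, and the posterior covariance of
each 6-h displacement, obtained from chained smoother gains) come from
the Rauch–Tung–Striebel smoother run over the union of fix times and
the prediction grid. Speed over ground is the geodesic displacement
between consecutive predicted positions divided by the interval.

Numerical notes: as β → 0 the exact discretisation formulas cancel
catastrophically (they approach the integrated-random-walk limit
`Q_xx = σ² dt³/3`), so below `β·dt = 10⁻⁴` the code switches to Taylor
series; observation variances are floored at 1 m² to keep the filter
non-singular on noiseless fixtures; a Nelder–Mead "degenerate simplex"
return on flat plateaus (e.g. exactly linear tracks, where σ² → 0) is
accepted after a verification restart.

## Movement persistence

Behaviour along the regular path is summarised by a persistence index
γ_t ∈ (0, 1) — 0 for meandering area-restricted search, 1 for directed
transit. With planar displacements `d_t`, the model is

d_t = γ_t · d_{t−1} + s_t · ε_t,  ε_t ~ N(0, σ_ε² I₂),

with `logit(γ_t)` evolving as a Gaussian random walk. Two choices
differ deliberately from a textbook implementation:

* **Multiplicative noise.** `s_t = max(|d_{t−1}|, half the track-median
  step length)`. With a constant noise scale in meters, slow residence
  steps (≈ 8 km per 6 h) carry almost no information next to 30 km
  transit legs, and the fitted field collapses towards the transit
  level; scaling by the step length equalises the information per step.
  The floor stops near-stationary steps (hundreds of meters) from
  exploding the scaled residuals.
* **Fixed smoothness.** The logit random-walk step SD defaults to 1
  (per 6-h step), allowing a behavioural switch to complete within a
  few steps. Selecting this smoothness by marginal likelihood is
  supported (`smoothness = "ml"`) but not the default: under abrupt
  regime switching the marginal likelihood systematically prefers
  over-smooth fields (profiling it on tracks with known regimes selects
  SDs near 0.1 and blurs switches over weeks). Only the noise scale
  σ_ε is estimated, by maximising the Laplace-approximated marginal
  likelihood; the inner mode is found by sparse Gauss–Newton (the
  Hessian is tridiagonal-plus-diagonal).

## Segmentation: phases and calving

Changes in the mean of a per-step series are found by penalized-contrast
segmentation: for each number of segments K the within-segment sum of
squares is minimised exactly by dynamic programming (no heuristics),
subject to a minimum segment length `Lmin` (default 8 steps = 2 days,
long enough to suppress single-step artefacts). Two selection rules for
K are provided:

* the classical normalized-contrast second-difference rule (threshold
  0.75), the default of `lavielle_segment()`;
* an incremental-drop rule — the largest K whose contrast decrease is
  at least 2% of the total, floored at `2·log(n)/n` to discount
  chance-level decreases on unstructured series — the default of
  `detect_migration_phases()`.

The second rule exists because migratory tracks *alternate*
(residence/transit/residence/…): isolating an interior segment requires
a pair of breakpoints, the one-step contrast drops alternate
small/large, and the second difference oscillates around zero, so the
classical rule under-segments exactly the structures this package is
for (on seven-regime tracks it selects K = 3 even on noise-free
persistence series).

Segments are labelled transit or residence by comparing their mean
persistence to the track median. Each breakpoint is then re-dated by
the best single mean-change split of the *speed* series within ±24
steps (6 days): persistence estimated from a smoothed path anticipates
departures and prolongs arrivals by up to a few days, because near a
regime switch the smoother already curves towards the upcoming transit
while speeds are still low; the speed series switches sharply at the
true boundary. Refinement is skipped when the local speed change is
immaterial (< 10% contrast reduction) and never reorders breakpoints.

Calving is dated by the same machinery on the southbound-leg speed
series with K = 2. The K-selection rules degenerate at Kmax = 2, so a
change is declared by the package's own documented rule: the single
best split must reduce the contrast by at least 5% (and the series must
not be constant); otherwise an explicit "no change detected" result is
returned. The speed entering this analysis is the current-corrected
swim speed when available, else speed over ground, and the choice is
flagged in the output.

## Ocean-current correction

Surface current vectors are attached to each step by nearest-neighbour
lookup, time first then space; ties go to the earlier record and the
lower cell index; masked cells fall back to the nearest valid cell
within a 3-cell radius (the fallback distance is recorded), and a step
with no valid cell within the radius is flagged and treated as zero
current. The swim (through-water) velocity is `ground − current`, where
the over-ground velocity vector is built from the geodesic distance and
initial bearing of the step, so with a zero current field the swim
speed reproduces the speed over ground identically. The current is also
decomposed into support (projection on the travel direction, positive =
pushing along the track) and a signed cross component (positive =
current pointing left of travel). Steps are classified resting
(V ≤ 0.5 m/s, threshold inclusive) or transiting (> 0.5 m/s). Currents
are assumed constant over each 6-h step and surface (0–5 m) currents
stand in for swim-depth currents.

## Bioenergetics

Maintenance follows Kleiber allometry, `BMR = 70 · M^0.75` kcal/day,
converted at 4,186.8 J/kcal — 668 MJ/day for the default 30,000 kg
female. The cost of overcoming drag at swim speed V is

P = λ / (2 ε_A ε_P) · ρ · S · C_d · V³   (W),

with defaults λ = 0.7 (active:passive drag), ε_A = 0.2 (aerobic), ε_P =
0.8 (propulsive), ρ = 1,027 kg/m³, C_d = 0.003, and wetted surface
S = 0.054·M^0.696 m² (recomputed whenever the mass changes). Per-step
energy is P·Δt; maintenance accrues per step (BMR/4 for 6-h steps) so
budgets over adjacent windows add exactly; stationary days are included
in maintenance. Gestation and lactation costs are *not* modelled —
budget reports flag that totals underestimate a reproducing female's
true expenditure.

Because the cube is convex, evaluating V³ at smoothed point-estimate
speeds is biased low. When the track carries the smoother's per-step
displacement covariances, `budget()` (by default) replaces each step's
V³ with the posterior expectation E[|v|³] under a Gaussian velocity
posterior, computed by 7-point tensor Gauss–Hermite quadrature. Under a
correctly specified state-space model this de-attenuates the cubic cost
exactly in expectation; see Limitations for how far that holds here.
Median/IQR speed summaries always use the plain point estimates. Two
per-day rates are reported (total/days and total/transiting-days),
since "per day" is ambiguous when stopovers are included.

Theoretical alternative-speed scenarios (`scenario_sweep()`) evaluate a
fixed-length leg at constant speeds: duration, transport cost,
maintenance over the (longer) duration, and the arrival delay relative
to the observed duration of that leg.

## Least-cost routes

The shortest route through water between two points is the exact
Dijkstra shortest path on the graph of water cells with depth > 10 m,
16-connected (knight moves included, reducing grid-direction bias;
8-connectivity available), with WGS84 geodesic edge lengths between
cell centers. Endpoints snap to the nearest admissible cell within 5
cells (coastal endpoints often fall on masked cells); snap distances
are reported. Route comparisons report the observed cumulative track
length, the direct least-cost distance, the via-stopover distance, and
the percentage excesses.

## The synthetic-data generator

`paper_like_scenario()` encodes a 321-day round-trip deployment with
the structure of a complete North-Atlantic humpback migration: 30 days
of winter-fjord residence; a 7-day transit at 1.9 m/s; a 15-day Iceland
stopover; a southbound transit (24 days at 1.7 m/s, then — from the
calving event onward — 37 days at 1.3 m/s); 16 days on the breeding
ground; a 71-day northward transit at 1.5 m/s; and a long Barents Sea
residence. True persistence is 0.9 in transit and 0.05 in residence
(area-restricted search is nearly directionless), residence speeds are
0.35–0.45 m/s, and within-phase speed fluctuations have a 25%
coefficient of variation. Truth is generated as per-phase vector AR(1)
displacements in the working plane (directed phases: waypoint heading
plus independent fluctuations, with the mean shrunk by `1 + cv²/2` so
the realized mean speed hits its target; residences: zero-mean AR with
Rayleigh-calibrated magnitude), and true step speeds are reported on
geodesics. Observation emulates a ~13 fixes/day duty cycle (Poisson
times), a realistic quality-class mix (5/10/15/15/25/30% for classes
3/2/1/0/A/B), log-normal error-ellipse sizes around Kalman-era CLS
magnitudes (250 m to 4 km semi-major by class), 1% gross outliers
(150–400 km) and 1% class-Z rows. The toy current field derives from a
smooth streamfunction (hence exactly divergence-free on its metric,
amplitude 0.1 m/s), and the toy bathymetry is constant-depth water with
polygonal land. One scenario seed drives everything through per-component
sub-seeds, so changing the observation model never perturbs the truth.

What the generator does **not** emulate: real coastline geometry, tidal
and depth-varying currents, within-6-h tortuosity (truth lives on the
6-h grid), duty-cycle gaps and haul-out patterns, correlated Argos
errors, or seasonal changes in fix quality. Passing end-to-end tests
therefore demonstrate that the estimation chain recovers the truth *of
this data-generating process* at realistic noise levels — not that it
is unbiased on real tracks, where the additional structure above enters.

## Problem sizes used by the tests

The suite fits the full 321-day scenario once (~4,200 fixes, 1,284
predicted steps) and reuses it across assertions; parameter-recovery
runs use 20 simulated tracks of 500 fixes; brute-force equivalence
checks use 200 random series (n ≤ 30) for segmentation, 100 random
20-fix tracks for the pre-filter, and 6×6 grids for path enumeration —
sizes at which the exhaustive oracles are exact and fast.

## Known limitations

* **Cubic-cost attenuation.** State-space smoothing shrinks
  step-to-step speed fluctuation (displacement error ≈ 3 km/step
  against ≈ 8 km/step true fluctuation at the default noise levels),
  and the cube amplifies the loss: the pipeline's E_COT lands 8–10%
  below the value computed from true swim speeds across seeds. The
  posterior de-attenuation recovers only ~1 percentage point, because
  the single-regime CTCRW posterior is overconfident for
  regime-switching truth (claimed displacement SD ≈ half the empirical
  one). Energy budgets from smoothed tracks — here and in the
  literature this workflow mirrors — should be read with that bias in
  mind.
* **Persistence near regime switches.** γ estimated from a smoothed
  path ramps into residence periods (the smoother anticipates
  departures); breakpoint dating relies on the speed-refinement step,
  and γ itself should not be over-interpreted within ±2 days of a
  switch. Residence-level γ is biased upward relative to a truth near
  zero (the index is bounded below and the smoothed path is locally
  smooth); contrasts between regimes remain strong.
* **Single-regime movement model.** One (β, σ) pair serves the whole
  track; the fitted velocity time scale (~30 h) is a compromise between
  transit and residence dynamics. Per-regime state-space models would
  sharpen both of the artefacts above at the cost of joint inference.
* **Currents.** Nearest-neighbour sampling of a surface field ignores
  path-integrated drift within a step and any depth structure.
* Budgets exclude gestation and lactation; totals are lower bounds for
  a reproducing female.
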