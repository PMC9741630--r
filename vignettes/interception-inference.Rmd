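---
title: "Inferring rainfall interception loss from eddy-covariance latent heat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring rainfall interception loss from eddy-covariance latent heat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When rain falls on vegetation, part of it is intercepted by leaves and
branches, stored briefly, and evaporated back to the atmosphere without ever
reaching the soil. This interception loss, written E~i~, is the first term
in the surface water balance during any rain event, yet it is invisible to
standard flux measurements: an eddy-covariance (EC) tower reports one bulk
latent heat flux (LE) in which transpiration, soil evaporation and
interception evaporation are mixed.

`eiflux` implements a separation strategy built on a counterfactual: train
one model of LE using only *dry* hours (it has never seen interception) and
a second using only *wet*, in-event hours (it has). Run both on identical
wet-hour forcing; the dry model predicts the LE that *would have occurred
without rain*, and the difference between the two predictions is an estimate
of the interception flux. Everything else in the package — quality control,
event segmentation, the canopy-water-storage latent variable, gridded
upscaling, rainfall-regime attribution — exists to make that subtraction
reliable and reusable.

## The physical core: a quadratic Penman-Monteith operator

Both models are *physics-constrained*: the machine-learned part predicts the
log surface resistance ln R~s~, and a Penman-Monteith (PM) operator maps
R~s~ to LE. Any prediction therefore conserves the surface energy balance
(H + LE = A, with A = R~n~ − G) and respects the diffusion form of
evaporation. The operator solves the coupled system

    H  = rho c_p dT / r_a
    LE = (rho c_p / gamma) (VPD + Delta dT + 0.5 k dT^2) / (r_a + R_s)
    A  = H + LE

for the surface–air temperature difference dT, where the saturation vapor
pressure curve is expanded to *second* order (curvature k = d²e~sat~/dT²)
rather than linearized as in the classical PM equation. The resulting
quadratic has two roots; `pm_forward()` selects the one that is continuous
with the classical solution as k → 0, in the numerically stable form
dT = −2c/(b + sqrt(b² − 4ac)). The inversion `pm_invert()` is closed-form:
the energy balance fixes dT from LE, the quadratic expansion gives the
surface vapor pressure, and the diffusion equation is solved for R~s~. The
pair is an exact algebraic bijection — the test suite verifies round trips
to better than 10⁻⁶ W m⁻² over R~s~ ∈ [0, 10⁵] s m⁻¹ — so the learned
resistance and the predicted flux are two views of the same quantity.

Fixed constants: c~p~ = 1013 J kg⁻¹ K⁻¹, air pressure 101.325 kPa (site
pressure is not among tower inputs), λ(T~a~) = (2.501 − 0.002361 T~a~)·10⁶
J kg⁻¹, γ = c~p~ P/(0.622 λ), dry-air density from the ideal gas law.
Aerodynamic resistance uses the neutral logarithmic profile with
d = 0.67 h, z~0m~ = 0.123 h, z~0h~ = 0.1 z~0m~, and wind speed floored at
0.5 m s⁻¹; stability corrections are deliberately out of scope. Because no
explicit quadratic-PM formula is in wide circulation, this construction —
a second-order Taylor expansion of the saturation curve with the
continuity-selected root — is the package's central interpretive decision,
and it is isolated behind `pm_forward()`/`pm_invert()` so an alternative
form could be swapped without touching any other module.

## Rain events, wet hours, and the eight rainfall descriptors

Wet hours are defined by a three-rule event scan of the hourly
precipitation series:

1. an event starts at the first hour with P ≥ 0.5 mm;
2. after the last qualifying rain hour a 6-hour tail is appended (12 hours
   when that hour falls at night, since drying is slower without radiation);
   any hour with P ≥ 0.5 mm inside the tail extends the event and restarts
   the tail;
3. events lasting longer than 60 hours are re-segmented into sub-events that
   start at P ≥ 1 mm and are spaced more than 6 hours apart, each receiving
   its own tail.

Design choices where the rules are silent: "night" means solar elevation
below 0° at the hour the last rain ceased; the 60-hour duration includes
tail hours; the re-segmentation is applied once, not recursively; a >60 h
span containing no P ≥ 1 mm hour is discarded with a warning. Runs of
consecutive rainy hours (P > 0) inside an event are *pulses*; hours with
0 < P < 0.5 mm can sit inside an event without being able to start one.
The detector is validated hour-for-hour against an independently written
brute-force implementation on hundreds of random series.

Within an event, each hour is described causally by eight rainfall
features: cumulative, mean and maximum hourly P since the event started;
the current hour's P; cumulative and maximum P of the last (possibly
ongoing) pulse; dry hours since that pulse ended; and the local solar
hour-of-day at which it ended. The end-timing feature is cyclic, so the
model consumes it as (sin, cos) of 2π·hod/24.

One consequence of the night-dependent tail is worth noting: adding rain to
an event does not always lengthen it, because a new daytime rain hour
carries a 6-hour tail where the previous nighttime rain carried 12. The
monotone "more rain, longer event" property holds exactly under a uniform
tail length, and the tests assert it in that regime.

## Tower preprocessing

The ingest module mirrors standard flux-network practice. Filters mask (not
delete, so the time axis survives for event detection): negative LE,
poor-quality flags (the flag cutoff is a configurable `qc_max`, default 1,
since networks differ), and freezing hours (T~a~ < 0 °C, excluding snowfall
interception, which is out of scope). IGBP vegetation classes are merged to
eight (WSA→SAV, OSH/CSH→SHU). Half-hourly records are aggregated to hourly
(states averaged, precipitation summed, an hour valid only when both halves
are).

Two LE corrections are provided. First, EC systems underestimate LE in
humid and rainy conditions; a per-site neural network (one hidden layer of
16 units — a deliberately small regressor) models the latent energy ratio
LER = LE/(R~n~ − G − H) as a function of RH and log-transformed hourly P
(offset 0.01 mm admits P = 0), and every hour's LE is rescaled so its LER
sits at the reference prediction for RH = 50 % and P = 0. The correction is
exactly neutral at the reference conditions and statistically neutral for a
site whose LER does not depend on RH or P. The model is fitted on all hours
with a positive available-energy denominator, not only wet ones. Second, a
Bowen-ratio closure redistributes the energy-balance gap so LE + H equals
R~n~ − G exactly while preserving H/LE; hours with LE + H ≤ 0 (common at
night, when available energy is near zero) are flagged and left unchanged.

## Hybrid models and the canopy-water-storage latent variable

HM~dry~ regresses ln R~s~ on standardized T~a~, VPD, R~n~, WS, LAI plus a
one-hot PFT encoding; HM~wet~ adds one more predictor, the canopy water
storage (CWS). PFT enters one-hot because a gradient-trained network needs
a non-ordinal encoding of categories. The loss is the mean squared error
between observed LE and `pm_forward(exp(ln R_s))`, differentiated
analytically through the quadratic operator, so the network is trained in
flux space while predicting in resistance space. Training details: two
hidden layers of 64 ELU units, Adam, mini-batches of 512, early stopping on
a 10 % validation split, all seeded; the net is warm-started by plain
regression on ln R~s~ targets obtained from the closed-form inversion of
observed LE, then fine-tuned under the physics loss (the warm start is an
initialization device; the physics loss is the objective that decides the
final weights). Hours where the inversion is undefined (the implied
surface–air vapor gradient is non-positive) are excluded from training but
still predicted. Training pools all sites into global models; uniform
sample weights.

CWS is not observable. On wet hours, the residual LE~obs~ − LE~HM_dry~ is
used as its proxy: whatever the dry counterfactual cannot explain is
attributed to evaporating canopy water. Negative proxies (measurement
noise) are removed from the CWS training set. A second network regresses
this proxy (kept in W m⁻², energy units; depth conversion happens only at
reporting) on LAI, PFT and the eight rainfall descriptors, making CWS
computable from rainfall history alone — which is what permits gridded
upscaling where no LE observations exist.

The hourly interception estimate is then
E~i~ = LE~HM_wet~ − LE~HM_dry~ on identical wet-hour forcing, with negative
differences removed (not zeroed), converted to depth by λ(T~a~), and summed
to events. Event ratios E~i~/P use the gross event precipitation including
any sub-threshold tail rain. The driver analysis fits the event ratio
against the three rainfall metrics (event total, maximum hourly and mean
hourly P) with a rational curve p/(x + q) — the simplest two-parameter
hyperbolic form consistent with a ratio that falls as intensity rises — and
against LAI and wind speed with straight lines, reporting two-sided Pearson
correlations pooled and per PFT.

## Upscaling to grids

`predict_grid_ei()` re-runs the site machinery per grid cell: events are
detected from the cell's own P series (same three rules), descriptors and
CWS are computed, and the two hybrid models are differenced. Three
grid-specific devices follow the site-to-grid scale mismatch:

* **CWS renormalization.** Grid rainfall statistics differ from tower
  statistics, so grid CWS is standardized by the mean/SD of CWS predicted
  over cells within a 5°×5° window around the training sites
  (`cws_window_stats()`), then mapped into the site-CWS space the wet model
  was trained in.
* **Vegetated-fraction masking.** Cell E~i~ is multiplied by the vegetated
  cover fraction f~veg~; prediction scales exactly linearly in f~veg~.
* **Light-rain correction.** Hours with 0 < P < 0.5 mm outside any event
  still intercept (sub-grid rain heterogeneity). Their E~i~/P ratio is
  interpolated linearly between f~veg~ at P → 0 (vanishing rain over canopy
  is fully intercepted) and a per-PFT anchor: the mean event ratio of
  events whose mean hourly P lies in [0.5, 0.7] mm, nominally the 0.6 mm
  point. The anchor sits just outside the corrected domain (0, 0.5); the
  same line is used across the whole domain regardless, which keeps the
  correction continuous and single-sloped.

8-day LAI composites are interpolated to hourly with a cubic smoothing
spline clipped at zero (a constant composite passes through unchanged);
dominant PFT is the post-merge argmax of cover fractions with ties broken
by the fixed PFT order; per-PFT default canopy heights stand in for cell
roughness since grids carry no tower geometry. Without a NetCDF reader in
the dependency set, the grid container is an in-memory structure (a cell
table plus per-cell hourly series) with a plain-CSV round-trip; it holds
everything the gridded operations need.

## Rainfall regimes and attribution

For trend work the package computes, per cell or site, a fixed intensity
threshold p90 — the 90th percentile (linear interpolation) of hourly P over
all rainy hours of the full record, requiring at least 100 rainy hours —
and annual fractions F~rain~ (hours with 0 < P < p90) and I~rain~ (hours
with P > p90) of the year's non-gap hours. The two fractions plus the
complement (P = 0 or exactly p90) partition every year exactly. Trends are
ordinary least squares with a two-sided t test; the reported percent change
is slope × (n − 1)/mean × 100, and a constant series returns slope 0 with
p = 1 by convention. Driver correlations are Pearson on raw (non-detrended)
annual series, matching a reading of year-to-year covariation rather than
detrended anomalies.

## The synthetic test bed

Because no tower archive ships with a known interception truth, the
`synth_config()`/`generate_site()` generator builds one. Meteorology:
seasonal and diurnal temperature sinusoids with AR(1) noise; a solar-arc
net radiation with per-day beta-distributed synoptic cloudiness (overcast
dry days exist, as at real towers) and stronger damping during rain; a
diurnal humidity cycle peaking near dawn, pushed to 92–100 % in and shortly
after rain, with VPD kept exactly consistent with T~a~ and RH; lognormal
wind; G = 0.1 R~n~. Rainfall: Poisson event arrivals (default 0.5 day⁻¹),
geometric rainy-spell durations (mean 4 h), gamma hourly intensities
(shape 1.2, scale 1.5 mm h⁻¹) — mid-latitude numbers chosen once as
representative and kept fixed.

The flux truth couples a prescribed smooth Jarvis-style dry surface
resistance R~s,dry~(VPD, R~n~, LAI) with a Rutter-type canopy bucket of
capacity S = 0.2 mm per unit LAI. Each hour the canopy intercepts
min(S − C, 0.7 P) (free throughfall 0.3), and evaporation is generated *on
the Penman-Monteith manifold*: the effective surface resistance is the dry
law scaled by the dry fraction, R~s,eff~ = R~s,dry~(1 − C/S), so a fully
wet canopy evaporates at the R~s~ = 0 potential rate, and the interception
flux is E~i~ = min(C, pm_forward(R~s,eff~) − pm_forward(R~s,dry~)) in depth
units. An earlier draft of the generator instead added the wet-canopy
potential on top of the dry flux; that composition draws on the available
energy twice, placing a substantial share of interception energy above the
R~s~ = 0 PM ceiling that *no* resistor-form model can reach, and thereby
building an irreducible negative bias into any energy-conserving estimator.
The resistance-scaling form keeps the additive identity the inference
relies on (observed LE = dry baseline + interception energy + noise, with
H closing the balance) while keeping every observation physically
reachable. Observation noise is additive Gaussian (default 10 W m⁻²) on LE.

What the generator does *not* emulate — and hence what passing tests do not
establish about real towers: instrument-specific spectral losses beyond the
LER-style bias (the correction is exercised on constructed series instead),
energy-balance non-closure (synthetic H closes by construction), advection,
footprint heterogeneity, gap structure, snowfall, and drip/stemflow timing
(intercepted water leaves the bucket only by evaporation). Recovery scores
on this test bed are an upper bound on real-world skill, not an estimate of
it.

## Verification scales and numerical choices

The shipped verification (also recomputed by `scripts/acceptance.R`) uses
problem sizes chosen to exercise every stage at meaningful statistics while
staying desk-sized: 10,000 random states for the PM round trip; 200 random
series against the brute-force event oracle; a 5-site × 2-year recovery
study at 10 W m⁻² noise for the end-to-end check (event-level truth
correlation ≥ 0.8 and mean relative bias within ±25 % are the pass marks,
with the fitted rational curve of E~i~/P declining in mean intensity);
1000 white-noise series of 21 years for the trend-test calibration; and a
single-cell grid tiled from one synthetic site for site/grid consistency
(r > 0.95, |bias| < 10 %).

Remaining numerical conventions: R~s~ is floored at 0 on inversion and the
network output is clamped to ln R~s~ ∈ [−5, 14]; ln R~s~ warm-start targets
floor R~s~ at 1 s m⁻¹; features are standardized by training-set mean/SD
with zero-SD guards; predictions more than 10 SD outside training support
warn but proceed (the grid pipeline inherits this); percentile convention
is R's default linear interpolation (type 7); rational fits run
Levenberg-Marquardt with median-based starting values and report
non-convergence rather than failing.

## Known limitations

* The quadratic-PM construction is an interpretation; its interface is the
  swap point if a canonical form is preferred.
* The CWS network sees rainfall history and vegetation state but not
  energy availability, so hour-scale CWS predictions are shrunken toward
  the mean; event sums inherit a modest low bias (about −10 to −15 % on the
  synthetic bed) even when the dry baseline is nearly unbiased.
* Global models are pooled across sites; no per-site fine-tuning, no
  uncertainty quantification, no ensembles.
* No atmospheric stability correction in r~a~; no gap-filling; no snow.
* Tower-mode annual fractions use non-gap hours and report coverage rather
  than imputing calendar hours.
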