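# eiflux

Rainfall interception loss — the part of rain that is caught by plant
canopies and evaporated back to the atmosphere without reaching the soil —
is invisible to an eddy-covariance tower: the measured latent heat flux
(LE) mixes transpiration, soil evaporation and interception evaporation
into one number. `eiflux` separates them. It is written for ecohydrologists
and flux-network scientists who want hourly and event-level interception
estimates (E<sub>i</sub>, and its fraction of gross precipitation
E<sub>i</sub>/P) from standard tower records, and who want to apply the
trained models to gridded forcing.

## Method

Two physics-constrained hybrid models are trained on disjoint parts of the
record:

* **HM<sub>dry</sub>** sees only *dry* hours (outside rain events) and
  learns the rain-free LE from T<sub>a</sub>, VPD, R<sub>n</sub>, WS, LAI
  and PFT;
* **HM<sub>wet</sub>** sees only *wet* hours (inside events, including a
  6 h drying tail, 12 h at night) and additionally receives the canopy
  water storage (CWS), a latent variable learned from LAI, PFT and eight
  descriptors of the rainfall history.

In both, a neural network predicts the log surface resistance ln R<sub>s</sub>
and a quadratic Penman–Monteith operator — the saturation curve kept to
second order, solved for the surface–air temperature difference — maps it
to LE, so every prediction satisfies H + LE = R<sub>n</sub> − G and the
diffusion form of evaporation. The loss is computed in flux space through
that operator. On identical wet-hour forcing,

E<sub>i</sub> = LE(HM<sub>wet</sub>) − LE(HM<sub>dry</sub>)

is the interception estimate: the dry model supplies the counterfactual LE
that would have occurred without rain. Around this core the package
provides tower QC and LE bias corrections (humidity/rain-dependent
underestimation, Bowen-ratio closure), the three-rule rain-event detector,
gridded upscaling with CWS renormalization, vegetated-fraction masking and
a sub-grid light-rain correction, rainfall-regime metrics
(F<sub>rain</sub>, I<sub>rain</sub>, p90 threshold) with OLS trend
attribution, and a synthetic flux-tower generator with a known
interception ground truth that makes the whole chain testable end to end.

## Worked example

```r
library(eiflux)

# one synthetic mid-latitude deciduous site, two years, known truth
cfg <- synth_config(n_years = 2, lat = 45, pft = "DBF", noise_sd = 10,
                    seed = 42)
site <- generate_site(cfg)

# full inference: QC -> events -> HM_dry -> CWS -> HM_wet -> Ei
pipe <- run_site_pipeline(site$series, config = hybrid_config(seed = 1))
et <- attach_truth(pipe$event_table, pipe$events, list(site$truth))

ok <- is.finite(et$Ei) & is.finite(et$Ei_true)
cat(sprintf("events detected:        %d\n", nrow(et)))
cat(sprintf("event Ei, estimated:    %.1f mm (truth %.1f mm)\n",
            sum(et$Ei[ok]), sum(et$Ei_true[ok])))
cat(sprintf("event-level Pearson r:  %.3f\n", cor(et$Ei[ok], et$Ei_true[ok])))
cat(sprintf("median event Ei/P:      %.1f%%\n", 100 * median(et$ratio[ok])))
cat(sprintf("dry-model holdout r2:   %.3f\n", pipe$models$hm_dry$metrics$r2))
```

Output:

```
events detected:        280
event Ei, estimated:    150.3 mm (truth 170.5 mm)
event-level Pearson r:  0.978
median event Ei/P:      5.9%
dry-model holdout r2:   0.984
```

Reading it: 280 rain events were detected over the two years; summed over
events, the inferred interception (150 mm) tracks the generator's truth
(171 mm) with an event-level correlation of 0.98; the median event loses
about 6 % of its rainfall to interception at this site; and the dry model
explains 98 % of held-out dry-hour LE variance. The modest low bias is
characteristic of the CWS stage (rainfall history alone cannot fully
resolve hour-scale evaporative demand); the methods vignette
(`vignettes/interception-inference.Rmd`) discusses it.

For gridded application, `grid_from_site()` / `forcing_grid()` build the
grid container, `cws_window_stats()` supplies the 5°×5° CWS
renormalization, and `predict_grid_ei()` returns per-cell hourly
E<sub>i</sub> masked by vegetated fraction, with `light_rain_anchor()` and
`light_rain_correction()` handling sub-event drizzle. Regime attribution
runs through `rainfall_threshold()`, `annual_fractions()`,
`linear_trend()` and `correlate_drivers()`.

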