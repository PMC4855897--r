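# dispersalSSF

Movement classification and habitat selection during ungulate dispersal,
from GPS telemetry.

Dispersal — a permanent one-way relocation from the natal range — is the
movement conservation corridors exist to serve, yet habitat-selection
parameters are almost always estimated from home-ranging animals. This
package implements the full analysis chain needed to ask whether selection
*during* dispersal differs from selection before and after it:

* **Telemetry core** — screening of gross GPS position outliers (the
  "tens-of-km round trip in 4 h" signature), step construction (length,
  duration, movement rate, turning angle, the ±10-min regularity rule), and
  net squared displacement (NSD) profiles.
* **Movement typing** — nonlinear least-squares fits of the four NSD
  shapes (constant residency, single-logistic dispersal
  `δ / (1 + exp((θ − t)/φ))`, double-logistic migration, linear nomadism),
  AICc ranking, rule-based classification into
  migrant / resident / disperser / exploratory / other, and extraction of
  the dispersal event window (the days the fitted sigmoid crosses 2.5% and
  97.5% of its asymptote) with 26-day before/after windows and time-matched
  residents.
* **Behaviour segmentation** — a per-animal random-intercept mixed model of
  movement rate across the four periods, and segmented (broken-stick)
  regression of the log-binned rate distribution; the breakpoint ψ
  (m min⁻¹) times the 120-min interval gives the short/long step threshold
  (7.118 m min⁻¹ → 854 m).
* **Fine-scale step selection functions** — matched sets of 1 observed +
  10 random steps drawn from leave-one-individual-out empirical kernels
  (50-m / 10° bins), conditional logistic regression
  `ŵ(x) = exp(β₁x₁ + … + βₚxₚ)` fitted by a Newton solver with exact
  observed information, two-stage REML random-effects pooling across
  individuals, and k-fold cross-validation scored by Spearman's r_S against
  a within-stratum permutation null (usefulness bar: mean r_S > 0.65 and
  above chance).
* **Broad-scale route selection** — each dispersal route against 10
  correlated-random-walk null paths built from the individual's own
  long-step histograms; per-individual binomial models and exact Wilcoxon
  signed-rank tests on the population coefficients.
* **A synthetic world** — landscapes (elevation, TRI ruggedness, canopy,
  distance-to-roads, monthly NDVI) and multi-individual GPS trajectories
  generated by a discrete-choice simulator under *known* selection
  coefficients, with 2-h fixes, collar-specific fix success (81.7% / 66.2%),
  and injected position outliers — so every estimator is testable against
  ground truth.

## Worked example

```r
library(dispersalSSF)

L   <- generate_landscape(extent_km = 120, res_terrain_m = 300,
                          res_ndvi_m = 500, rng_seed = 11)
cfg <- simulation_config(rng_seed = 9)
tr  <- simulate_trajectory(L, "disperser", cfg, animal_id = "elk001", seed = 9)

scr <- screen_outliers(tr)
nsd <- compute_nsd(scr$trajectory)
cl  <- classify(fit_movement_models(nsd), nsd)
ev  <- extract_dispersal_event(nsd, cl)
print(cl)
print(ev)
```

```
<movement_classification> disperser (sigmoid_plateau)
<dispersal_event> day 57 to 98 (2008-05-28 to 2008-07-08), 41.7 km straight line, completed
```

The simulated male's year of 2-h fixes (1,655 retained after 66.2% fix
success; 6 injected outliers removed by screening) is classified as a
completed dispersal: its NSD profile is a single sigmoid rising to a
sustained plateau, and the event window — the days the fitted sigmoid
crosses 2.5% and 97.5% of its asymptote — brackets a 41.7-km straight-line
relocation. `make_period_windows(ev)` then yields the 26-day before/after
windows, and the window's 203 regular steps (mean rate 171 m h⁻¹, far above
home-ranging rates) feed the segmented-regression split and the SSF models.

`run_pipeline(pipeline_config(...))` runs the whole chain on a simulated
cohort — screen → classify → match residents → rate model → segmented split
→ the eight SSF models (dispersers and matched residents × before / during /
after, plus long/short during-dispersal steps) → broad-scale CRW test — and
writes per-stage CSV reports plus a `manifest.json` whose digests reproduce
bit-identically for a given config. A shell entry point is provided:

```sh
Rscript scripts/run_pipeline.R --out pipeline_out --seed 1
```

## Documentation

The methods vignette (`vignettes/dispersal-analysis.Rmd`) describes the
models, the synthetic world and its deliberate simplifications, every
tunable default, and the package's numerical choices.
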