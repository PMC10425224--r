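# cottonwl

Functional relationships between waterlogging duration and early-season
cotton growth and physiology, packaged for crop-model development.

Cotton is unusually intolerant of waterlogged soil in the weeks after
sowing: ponded water drives the root zone anoxic within days, and root
growth, nutrient uptake, photosynthesis and ultimately phenology follow.
Process-based cotton models (GOSSYM, OZCOT, CROPGRO-class) currently lack
the duration–response functions needed to simulate this. `cottonwl` is for
crop modellers and plant stress physiologists who need those functions in
a testable, reusable form.

## What it implements

The core quantity is the **waterlogging stress response index** of a
parameter *p* after *d* days of waterlogging,

```
WSRI_p(d) = mean(P_p | d days) / mean(P_p | 0 days)
```

(1 = unaffected, 0 = fully limited; stress-induced traits may exceed 1),
together with the three response families fitted to it —
linear `y = s·x + i`, quadratic `y = a·x² + b·x + c`, and exponential
decay `y = a·e^(b·x)` — and:

* a packaged registry of 26 published response curves (plant height,
  organ dry weights, root morphology, pigments, gas exchange and
  fluorescence), with printed coefficient ambiguities resolved by a
  documented rule and flagged, never silently altered;
* least-squares fitting of all three families (closed-form linear and
  quadratic, Levenberg–Marquardt exponential with log-linear
  initialization), R², and parsimony-tempered model selection;
* a soil-oxygen model calibrated to the observed dynamics (zero oxygen
  after 5 days of waterlogging, recovery within 2 days of release) with
  anoxic-day accounting;
* squaring phenology: fits to the observed first-square delays, with the
  never-squared treatments handled as censored;
* a synthetic-data generator reproducing the 8-treatment × 5-replicate
  experimental design, so every pipeline stage is testable without any
  download;
* a minimal daily-step growth simulator applying the photosynthesis curve
  as a stress multiplier to potential growth.

## Worked example

```r
library(cottonwl)

reg <- load_registry()
reg
#> <curve_registry> 26 curves (exp_decay: 5, linear: 15, quadratic: 6)
#>   version: published compilation, as printed 2023

reg$entries$P          # leaf photosynthesis; printed columns re-oriented
#> <response_curve> P (Leaf photosynthesis)
#>   y = -0.051 x + 1.2   R^2 = 0.59
#>   flags: column_swapped

evaluate_curve(reg$entries$PH, 14)   # plant-height WSRI after 14 d
#> [1] 0.4652
percent_change(reg$entries$PH, 14)   # i.e. a 56% height reduction
#> [1] 55.94697

# synthetic experiment -> WSRI -> refit with the published families
tab  <- generate_dataset(generator_config(seed = 42))
wsri <- compute_wsri(tab)
all(wsri$index[wsri$duration == 0] == 1)   # control index exactly 1
#> [1] TRUE
fits <- fit_wsri_table(wsri, mode = "published_families")
round(fits$LA$curve$coefficients, 3)       # leaf-area decay, refitted
#> amplitude      rate
#>     1.002    -0.153

# soil oxygen and phenology
anoxic_days(14, oxygen_params())           # 9 anoxic days in a 14-d treatment
#> [1] 9
fit <- fit_square_timing()
predict_square_day(fit, 10)$day            # first square, 10-d treatment
#> [1] 37

# forward demonstration: stressed vs potential biomass at day 30
simulate_growth(wl_schedule(duration = 14))$relative_biomass
#> [1] 0.8879
```

The refitted leaf-area amplitude above is ~1 rather than the printed
0.977 for a structural reason: WSRI data are renormalized by the observed
control, so curves are recovered up to their value at 0 days (and the 5%
replicate noise perturbs the rate slightly). Refitting noiseless WSRI-space points
(`generate_wsri_points()`) recovers all 26 printed coefficient sets to
machine precision; see the methods vignette.

The numbered scripts under `analysis/` run the full workflow (registry
report, synthetic experiment, WSRI and refits, oxygen, phenology, growth
simulation) and write their tables under `results/`.

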