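---
title: "Modelling the cotton waterlogging response: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cotton waterlogging response: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cottonwl)
```

## The problem and the index

Cotton is among the row crops most sensitive to waterlogging, especially in
the first weeks after sowing, when ponded water drives the root zone from
hypoxia into full anoxia within days. Process-based cotton models need
*functional relationships* — curves linking the duration of waterlogging to
each growth and physiology parameter — before they can simulate that damage.
This package implements such a toolkit around the **waterlogging stress
response index**:

$$\mathrm{WSRI}_{p}(d) \;=\; \frac{\bar{P}_{p}(d)}{\bar{P}_{p}(0)},$$

the mean of parameter $p$ under $d$ days of waterlogging divided by its mean
in the 0-day control. The index is 1 where stress is not limiting and 0
where it is fully limiting. We deliberately allow values above 1: the
stress-protective pigments (flavonoid and anthocyanin indices) and
nonphotochemical quenching (NPQ) genuinely rise under stress, so the nominal
$[0, 1]$ range is read as describing declining parameters only. `compute_wsri()`
normalizes by the *mean* of the control cell, not by per-replicate pairing —
this matches the index's definition; replicate dispersion is carried
alongside (`sd_value`) for optional weighting rather than folded into the
index.

Because the control index is the control cell divided by itself, it is 1
*bit-exactly*, and the tests assert `identical(x, 1)` rather than numerical
closeness.

## Response families and the packaged registry

WSRI-versus-duration relations use three families, with $x$ the days of
waterlogging:

* linear, $y = sx + i$ — root length/surface/volume, pigments, all gas
  exchange and fluorescence parameters;
* quadratic, $y = ax^2 + bx + c$ — plant height, stem diameter, leaf
  number, root dry weight, tips, crossings;
* exponential decay, $y = a e^{bx}$, $b < 0$ — leaf area and the organ dry
  weights.

The package ships a registry of the 26 published curves for an early-season
(15 days after sowing) waterlogging episode, transcribed exactly as printed
and re-interpreted only where interpretation is unavoidable:

* **Linear coefficient orientation.** The published table states
  $y = ax + b$, but rows such as leaf photosynthesis $(1.2, -0.051)$ are
  only physically sensible read as $(\text{intercept}, \text{slope})$ — an
  unstressed photosynthesis index of $-0.051$ is meaningless, one of $1.2$
  is a fit's intercept near 1. `disambiguate_linear()` therefore picks the
  orientation whose intercept is nearest 1 (ties keep the stated reading),
  because the index is 1 at zero stress by construction. Re-oriented rows
  are flagged `column_swapped`; the rule is deterministic and documented
  rather than per-row judgement.
* **Direction conflicts.** Chlorophyll and the nitrogen balance index carry
  positive slopes after disambiguation although both are described as
  declining. We keep the printed values (flag `direction_conflict`) and
  offer `load_registry(negate_direction_conflicts = TRUE)` as an explicit
  opt-in; silently "fixing" printed numbers is worse than exposing them.
* **The NPQ row.** $(0.051, 0.052)$ yields an unstressed value of
  $\approx 0.05$ under either orientation — plausibly a typo for an
  intercept near 1.05, but unverifiable, so it is stored as printed and
  flagged `intercept_anomaly`.

Evaluation (`evaluate_curve()`) is `raw` by default so the fits are
reproduced exactly; `clamp_nonneg` floors at 0 (used when curves scale
physical means — the root-crossings quadratic dips to $-0.047$ at 14 days);
`clamp01` additionally caps at 1 (used when a curve acts as a stress
multiplier). Durations are real-valued so the curves can drive daily
simulation, not only the experimental grid.

## Fitting and model selection

Linear and quadratic fits are exact ordinary least squares; exponential
decay is Levenberg–Marquardt nonlinear least squares started from a
log-linear regression of $\log y$ on $x$ over the points with $y >
10^{-9}$ (falling back to amplitude $=\max y$ and a rate from the
first/last positive pair when that regression is degenerate). The start is
derivative-free and, on noiseless decay data, already essentially exact,
so the iterative refinement is a polish step. Convergence uses a relative
coefficient tolerance of $10^{-10}$ with a 200-iteration cap; hitting the
cap is reported (`converged = FALSE`), not raised. Fits are unweighted by
default — the source analysis states no weighting — with optional case
weights accepted.

$R^2 = 1 - SS_{res}/SS_{tot}$ is taken about the mean index and may be
negative for a poor nonlinear fit; constant responses make it undefined and
raise an error rather than returning a sentinel. The published $R^2$
values are *not* reproduced or asserted anywhere: they were computed from
unpublished raw means, so their provenance cannot be checked.

`select_model()` fits all three families and keeps the highest $R^2$,
except that a simpler family wins whenever it comes within 0.01 of the
best. The margin exists because a quadratic can always edge a line by a
vanishing amount on noisy data; 0.01 is small relative to the spread of
published $R^2$ (0.41–0.98) yet large enough to make the parsimony
preference effective. The source fixes families per parameter without
stating a rule, so selection is offered as a convenience
(`mode = "auto_select"`), with the published assignment
(`mode = "published_families"`) as the reproduction path.

## Soil oxygen and anoxia accounting

The observed calibration is narrative, not parametric: oxygen took about
five days of waterlogging to reach zero and returned to ambient within one
to two days of release. The published oxygen-response figure prints no
coefficients, so the module exposes the *shape* as configuration instead of
hard-coding an unverifiable equation. The default is linear depletion from
ambient 20.9% to 0 over `t_depletion = 5` days, holding at 0 while
waterlogged, then linear recovery to ambient over `t_recovery = 2` days. An
exponential shape is available for soils that approach but never reach
zero; its rate is set so the curve passes `anoxia_threshold + 1%` of
ambient at `t_depletion`, and a positive threshold should be set with it.

Anoxic days are counted over left-closed day bins $[t, t+1)$ evaluated at
the bin start, within the treatment window. This convention reproduces the
two observational anchors simultaneously: the 2- and 4-day treatments
record zero anoxic days, and a boundary treatment exactly as long as the
depletion time also records zero (oxygen reaches zero at the moment of
release). Under the defaults the count reduces to the closed form
$\max(0, d - 5)$. The anoxic-days-versus-duration relation over the eight
design durations is then captured by a quadratic fit ($R^2 \approx 0.99$),
mirroring how such hinge-shaped counts are usually summarized.

## Phenology: delay of the first square

The squaring observations are few and partly censored: 25 days from
emergence in the control and 2-day treatments, delays of 2 and 4 days at 4
and 6 days of waterlogging, and no squares within the 30-day window for
the 8–14-day treatments. Censored treatments are *excluded* from fitting,
never imputed — with four uncensored points and an unknown generating
function, imputation would manufacture information. The default family is
quadratic, consistent with the accelerating delay; the fit on the four
points is $(0.125, -0.05, 24.9)$, anchoring the control at 25 days
(half-away-from-zero rounding) and increasing monotonically across whole
days of the treatment range. (Between 0 and 0.2 days the parabola dips by
0.005 days — numerically irrelevant at day resolution, which is why
monotonicity is asserted on whole days.)

The source's own extrapolations for the censored treatments (32, 37, 43,
50 days) cannot all be reproduced by any single family fitted to the four
printed points — our quadratic gives 32.5, 36.9, 42.3 and 48.7 — so they
are treated as documentation, not test targets. Extrapolation beyond 6
days is clearly labelled as such in the analysis output.

## The synthetic experiment generator

No replicate-level data are deposited, so the package generates its own:
the full design (durations 0–14 by 2, five replicates, 26 parameters) with
cell means $\mu_{p}(d) = m_p \cdot \max(0, f_p(d))$, where $m_p$ is the
control mean and $f_p$ the registry curve, and replicate noise
$\mathcal{N}(\mu, (\mathrm{CV}\cdot\mu)^2)$ floored at 0. Choices, made
once:

* **CV = 0.05.** The source reports no dispersion; 5% is a typical
  replicate CV for controlled-environment physiology measurements, large
  enough to exercise the fitting stack and small enough that the floor at
  0 never activates (all positive means exceed 5 standard deviations).
* **Control means.** Only the mainstem leaf count (9.4) is a published
  control value; the other 25 are labelled synthetic placeholders of
  plausible magnitude (the `source` attribute and the file metadata say
  so). Downstream results are insensitive to them: WSRI is a ratio.
* **Independence.** Replicates are independent; no pot or block effect is
  simulated, since the design analysis is out of scope here.

Generation is a pure function of the seed (`withr::with_seed`), leaving
the caller's RNG untouched.

One structural point deserves emphasis. The registry curves are *fits*, so
none passes exactly through 1 at zero days (plant height starts at 1.056,
NPQ at 0.052). Data generated through physical means and renormalized by
the observed control therefore yield WSRI values equal to
$f_p(d)/f_p(0)$, not $f_p(d)$ — a ratio-normalized version of the curve.
The noiseless dataset round-trip accordingly recovers each curve *up to
that normalization* (the tests compare the pipeline against an oracle fit
of the renormalized trajectory), while exact recovery of the printed
coefficients is demonstrated from WSRI-space generation
(`generate_wsri_points()`), where no renormalization intervenes. Passing
these tests shows the estimation machinery is faithful; it does not show
the curves describe any real cotton crop beyond the experiment they came
from.

## The forward simulator

`simulate_growth()` is a deliberately minimal demonstrator of how the
curves enter a crop model through the carbon-supply route: each day's
potential biomass increment is multiplied by the photosynthesis stress
factor, the `P` curve evaluated at elapsed waterlogging days and clamped
to $[0, 1]$. Carbon allocation among organs is left unmodified — organ dry
weights responded in similar proportion, so re-partitioning is
unnecessary at this growth stage. Two open choices:

* **Post-release behaviour.** Soil oxygen recovery is quantified; *plant*
  recovery is not. The default holds the stress factor at its
  end-of-treatment value (conservative), with an optional linear
  relaxation to 1 over `recovery_days`.
* **Stress driver.** Elapsed treatment duration by default, because that
  is how the curves were parameterized; `driver = "anoxic_days"`
  substitutes the oxygen module's count, which lags elapsed time by the
  depletion phase and is therefore milder.

Only the single-factor route is implemented: how several curves (P, Gs,
LA) should *combine* is unspecified by the underlying study, and
multiplying correlated stress factors would double-count damage.

## Numerical conventions and degenerate inputs

Empty duration vectors, negative durations, missing control cells, zero
control means, censored-only phenology inputs and constant-index fits all
raise typed, named errors early. Missing cells propagate as absent rather
than imputed. Negative measurements produce a warning and a retained
negative index. Rounding of predicted days is half-away-from-zero.
Coefficient recovery tolerances in the tests are $10^{-6}$ for the
closed-form families and $10^{-4}$ for the iterative exponential fits.

Problem sizes used by the checks: the eight design durations throughout;
200 Monte-Carlo repetitions per family for the noisy-recovery coverage
check (noise sd 0.03 on indices, means of 5 replicates, fixed seed;
recovered slope/rate within 3 standard errors of truth at least 95% of
the time); 500 replicates for the law-of-large-numbers check on the
generator.

## Limitations

The curves describe one cultivar, one soil, one early-season episode
assessed 30 days after sowing; nothing here extrapolates to flowering or
boll development, fiber quality, nutrient dynamics, or field water-table
regimes. The oxygen model is a calibrated shape, not diffusion physics.
The generator's dispersion is conventional, so power-like conclusions from
synthetic data reflect that convention, not measured variability. The
simulator demonstrates coupling; it is not a crop model.
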