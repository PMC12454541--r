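---
title: "Methods: the energetics-based activity model and deviation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the energetics-based activity model and deviation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winterbudget)
```

## The daily energy budget

`winterbudget` treats a winter day as `t` active hours and `24 - t`
inactive hours. While active, an individual earns metabolizable energy at
rate `I` (kJ/h) and spends at `A * RMR`, where the activity multiplier `A`
collapses all active behaviours (foraging, travel, vigilance) into one
state — the model is deliberately coarse-grained to the daily scale at
which accelerometer budgets are summarized. While inactive it spends `RMR`.
Below the lower critical temperature `TLC`, a Scholander–Irving
thermoregulatory term `C * (TLC - Ta)` is added to expenditure: fully,
during activity, and attenuated by the thermal-refuge quality `Q` during
rest, since a den or form shelters a resting animal but not a moving one.
All rate parameters scale with body mass as `X0 * M^b`.

Assumptions worth stating explicitly:

* mean daily temperature is a sufficient thermal statistic — no sub-daily
  budgeting, wind chill, or body-temperature dynamics;
* intake rate is constant within a winter (the calibration grid of
  `calibrate_intake()` exists precisely because `I` is the least certain
  parameter);
* the budget is linear in `t`, so the marginal value of an active hour,
  `d(NEG)/dt = r_a + r_i`, does not depend on `t` itself.

Setting daily net gain equal to the species target — 0 for an animal with
no usable fat reserve, `-f * 398 * M^0.75` kJ for one drawing a fraction
`f` of its maintenance from fat — gives the closed form implemented in
`required_activity_time()`:

```
t* = (target + 24 * r_i) / (r_a + r_i)
```

### Conventions at the boundaries

* **Cold branch at equality.** The cold expressions apply for `Ta <= TLC`
  exactly; both branches agree at `Ta = TLC`, so the rates are continuous.
* **Infeasible days.** When `r_a + r_i <= 0`, or the unclamped `t*`
  exceeds 24 h, balance is unattainable; the prediction is reported as
  `t_pred = 24` with `feasible = FALSE` and kept in every downstream
  table. Cold days are data, not errors, and the deviation analysis can
  include or exclude them explicitly.
* **Fat floor.** When the subsidy covers the whole inactive-day cost
  (`target + 24 * r_i <= 0`), `t_pred = 0`, feasible.
* **Tolerances.** The closed form is the implementation; an interval-
  halving root-finder exists only in the test suite as an independent
  oracle. The round-trip identity `NEG(t*) = target` is enforced to
  1e-9 kJ, and closed-form/bisection agreement to 1e-6 h, over randomized
  parameter sweeps.

## Parameter sets

Two defaults ship in `inst/extdata/species_defaults.conf` and as
`hare_params()` / `porcupine_params()`.

The **hare-like** set (no fat subsidy, `Q = 0`, `TLC = -5` °C) is
*calibrated*, not measured: its three free rates at the reference mass
(1.35 kg) are the exact solution of three balance-point constraints —
balance time 10.54 h in the TNZ, daily expenditure 754.3 kJ at balance,
and 56 kJ of net gain per 1.3 h of activity. Within the TNZ these are
linear in `(RMR, A*RMR, I)`, so `solve_balance_constraints()` recovers
them exactly:

```{r}
solve_balance_constraints(t_star = 10.54, ee_day = 754.3, marginal = 56 / 1.3)
```

giving `RMR0 = 15.105`, `I0 = 57.142`, `A = 2.506` at `b = 0.75`. The
acceptance suite re-derives this solve and checks the shipped set
reproduces all three observables simultaneously. `C0 = 0.8` and
`TLC = -5` °C are plausible winter-acclimation values for a well-insulated
1–2 kg lagomorph; they control only the below-TNZ branch.

The **porcupine-like** set (`f = 0.10` of the 398·M^0.75 kJ/day maintenance
from fat, `Q = 0.8`, `TLC = -15` °C, `RMR0 = 8`, `I0 = 41`, `A = 2` at
M ≈ 8 kg) is configuration, not ground truth: the values are scale
arguments for a large, den-using, winter-hypophagic herbivore, chosen so
the balance time lands in the observed few-hours range, and flagged as
placeholders wherever they appear. Whether the refuge quality of a real
den is nearer 0.6 or 0.95 is an empirical question the package does not
answer; `Q` only needs to be high (and `TLC` low) for the species contrast
the generator is built to express. The fat fraction has a documented
0.20 variant for sensitivity analysis, and a larger subsidy can only
lower the predicted activity time (a tested monotonicity).

The scaling exponent `b = 0.75` is applied uniformly to `I`, `RMR` and
`C`. Per-parameter exponents are supported by editing the config, but with
cohort mass ranges this narrow the choice is inconsequential and a single
exponent keeps the parameter count honest.

## The synthetic-data generator

`simulate_environment()`, `simulate_cohort()` and `simulate_activity()`
are first-class, tested code: they define the conditions under which every
downstream claim is demonstrated.

The weather model is deliberately generic mid-continental winter: a linear
seasonal temperature ramp (−2 °C on December 1, −0.08 °C/day) with AR(1)
anomalies (φ = 0.7, innovation SD 3 °C), lognormal daily wind (median
8 km/h), snow depth as a reflected random walk from 15 cm, Beta(2, 2)
cloud cover, a 29.53-day sinusoidal moon cycle, and night length ramping
linearly 15.0 → 10.5 h over days 0–135 (≈45° N). Lunar luminosity is the
multiplicative occlusion `moon_frac * (1 - cloud)` — the simplest
combination that is monotone in both drivers and vanishes under full
overcast; it is a configurable hook, not a claim about optics.

Activity is the generative inverse of the analysis model: the energetics
prediction for that day and individual, plus linear covariate effects, a
seasonal (and sex-interacting) trend, a per-individual Normal(0, σ_b)
intercept, and Normal(0, σ_e) residual noise, clamped to [0, 24] (clamped
rows are flagged so recovery tests can avoid heavy-censoring regimes). A
fixed `nocturnality` share of each day's activity is placed at night,
clipped to the night- and day-length bounds — proportional placement, not
sunrise/sunset scheduling, which is sufficient for the diel summaries the
package computes and nothing more.

Default study conditions mirror the data volumes the method is meant for:
29 hare-like individuals × 28 days (~810 individual-days) and 21
porcupine-like × 18 days (~380). Effect presets: the hare-like generator
uses wind and snow effects of −0.065 h per unit (so a 20-unit change moves
activity by 1.3 h), a weaker lunar effect (−0.3 h per luminosity unit), a
mild seasonal decline, and σ_b = 0.46 h against σ_e = 1.0 h (intercept
share ≈ 18% of residual variance); the porcupine-like generator has null
environmental effects, a mild positive seasonal trend with a small male
surplus, and σ_b = 1.05 h against σ_e = 1.2 h (share ≈ 43%). The
generator reproduces the *structure* of field data — shared environmental
forcing versus idiosyncratic individuals — not its measurement error:
there is no accelerometer misclassification, no missing days, no
staggered collar deployments, no spatial heterogeneity. Passing recovery
tests therefore show the estimator is consistent under the assumed model,
not that field estimates are unbiased.

## The deviation pipeline

`compute_deviations()` subtracts predicted from observed activity
(positive = more active than balance requires). The analysis then:

* **subsets to the TNZ** (`subset_tnz()`): below `TLC` the prediction
  itself moves with temperature, so environmental effects on the deviation
  are confounded with thermoregulation; the main fit uses warm days only.
  The full-data variant instead keeps everything and adds the binary
  below-TNZ indicator. Infeasible (capped) days are retained by default —
  there is no principled exclusion rule, and the flag makes the
  alternative a one-line filter; the suite exercises both.
* **standardizes covariates** (`standardize_covariates()`) by mean and
  *sample* SD (n − 1) on the rows actually fitted, storing both for exact
  back-transformation (`raw_scale_effects()`; the identity `β_raw = β_z /
  SD` is tested against a refit on raw covariates to 1e-6).
* **fits the LMM** via `lme4::lmer`: REML for the reported variance
  components, with AIC/AICc computed from an ML refit by default because
  REML likelihoods are not comparable across fixed-effect structures
  (`ml_for_ic = FALSE` restores pure-REML criteria). Wald
  normal-approximation intervals and p-values — documented as approximate;
  with ~30 groups and hundreds of observations the difference from a
  degrees-of-freedom-corrected test is immaterial for the effect sizes of
  interest.
* **partitions variance**: `random_intercept_share()` is
  σ²_b / (σ²_b + σ²_ε) — the share of *fixed-effects-unexplained*
  variance due to stable individual identity, invariant to shifting all
  deviations by a constant.
* **translates to energy**: `coefficient_to_energy()` multiplies a
  raw-scale coefficient by a covariate change, then by the budget slope
  `r_a + r_i`, and expresses the results relative to the balance activity
  time and to the daily expenditure at balance
  (`A*RMR*t* + RMR*(24 - t*)` in the TNZ).

## Synchrony and diel summaries

Same-day pair enumeration emits each unordered pair of individuals once,
ordered lexicographically (`k` individuals on a day give `k(k-1)/2`
pairs), and the synchrony statistic is one pooled Pearson correlation
over all pair observations, not an average of per-day correlations. The
single-ordering convention makes the statistic very slightly dependent on
labels; the suite bounds that sensitivity by permutation, and
`pair_ordering = "both"` gives the exactly label-invariant symmetrized
variant. The night-use proportion is the mean of per-record
`t_night / night_h` ratios, with the ratio-of-sums alternative reported
alongside.

## Problem sizes and limitations

The test suite runs the solver sweeps at 10⁴ random draws (round trip to
1e-9 kJ), 500–800 bisection comparisons, and the recovery study at 100
replicates per species at the default cohort sizes, with the synchrony
contrast checked on one default-span hare-like study (>10⁴ pairs) and a
48-day porcupine-like study. The acceptance script averages the fitted
quantities over five replicate studies per species and computes synchrony
on one full-winter (120-day) study per species, where the pooled pair
correlation is stable across realizations. These sizes were chosen as the
smallest at which the Monte-Carlo assertions are stable.

Known limitations: no sub-daily energetics or behaviour-specific costs; no
wind-chill or radiative physics; residuals are assumed independent across
days within an individual (no temporal autocorrelation structure); no
multiple-testing adjustment across covariates; and the porcupine-like
parameter set is illustrative configuration, so quantities derived from it
(its CV, its balance time) characterize the package's behaviour, not any
real population.
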