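---
title: "From land-system scenarios to regional temperature attribution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From land-system scenarios to regional temperature attribution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pftclim)
```

## Scope

`pftclim` implements the analysis chain that sits downstream of a coupled
regional Earth system model experiment in which alternative land-system
scenarios are prescribed as plant-functional-type (PFT) maps. The package
covers five stages — translation, transitions, energy-balance decomposition,
attribution, and regional statistics — plus a synthetic generator that
emulates the full input stack with known ground truth. It does not run any
atmosphere or land model physics, does not fit habitat-distribution models,
and does not allocate land systems; those stages produce the *inputs* this
package consumes.

## Translation of land systems into PFT maps

Each fine-grid cell holds one categorical land-system code. Translation
proceeds in five steps:

1. **Habitat assignment.** A crosswalk constrains each land-system code to a
   set of candidate habitat types; the cell receives the candidate with the
   highest suitability score at that cell (ties resolve to the lowest
   habitat code, making the map deterministic). This is a deliberate
   stand-in for ensemble habitat-distribution modelling: it preserves the
   interface — one habitat per cell, conditioned on land system and local
   environment — without statistical model fitting.
2. **Composition from plots.** Habitat-level PFT composition is the plot
   archive average: species percent covers are mapped to PFT slots, summed
   within a plot, and averaged across the habitat's plots with equal plot
   weights. Equal weighting is the simplest defensible reading of
   "averaging across plots"; cover-weighted or area-weighted alternatives
   would require plot metadata the archive does not guarantee.
3. **Vertical-layer adjustment.** Raw covers can exceed 100% because
   vegetation layers overlap, but the land model sees only the highest
   layer. We resolve this by top-down occlusion: trees claim
   `min(total tree cover, 100)`%, distributed among tree PFTs
   proportionally to raw covers; the residual is offered to shrubs, then
   herbs; the unclaimed remainder is bare ground. The output is an exact
   unit-sum fraction vector. The proportional-within-layer rule is the
   package's own resolution of an under-specified step; any rule that
   honours "highest layer wins" and keeps unit sums would be admissible,
   and this one is the simplest that treats PFTs within a layer
   symmetrically.
4. **Land units.** Cropland habitats populate the crop land unit, other
   vegetated habitats the natural-vegetation unit; ice and urban cells pass
   through unchanged. Within each land unit, PFT fractions sum to 1 at
   every coarse cell — the constraint the land model imposes.
5. **Aggregation.** Fine cells are equal-area, so coarse fractions are
   arithmetic block means; land-unit area fractions are the tag shares.
   Grids are row-major with 0-based block arithmetic and cell-centre
   registration throughout.

## Net land-cover transitions

The 17 PFT slots aggregate into 7 categories: needleleaf tree, broadleaf
tree, shrub, grass (herbs excluding annual crops), rainfed crop, irrigated
crop, and bare ground. In fractional maps nothing identifies *which* cover
replaced which, so net transitions are resolved per cell by a greedy
matching: repeatedly pair the most-increased with the most-decreased
category, record a transition of the smaller magnitude, and update
residuals until all change is captured (residual tolerance 1e-12, far
below any ecological signal; ties break by the fixed category order above).
Each iteration zeroes at least one category, so a cell records at most 6
transitions, and recorded transitions exactly reconstruct the per-category
change.

For regression use, each unordered pair is oriented by its dominant
direction over the region (the direction with more total transitioned
area), and the per-cell predictor is the signed difference
`x = f_dominant − f_opposite`, in units of cell fraction. With all seven
categories active and the rainfed/irrigated pair empty, 20 transition
types exist. The signed encoding is an interpretation of "named by the
dominant direction": it lets a single coefficient serve both directions of
a pair, with the reverse direction entering with negative sign.

## Surface energy balance decomposition

The surface balance `(1−α)SWdown + LWdown − εσTs⁴ = LH + SH + G` (with
ε = 1) closes by construction in the coupled model, so G is computed as the
residual. Linearising the emitted longwave term gives the decomposition of
a scenario-minus-reference skin temperature difference:

```
ΔTs ≈ λ · ( −ΔLH − ΔSH − ΔG − SWdown·Δα     [surface contribution]
            + (1−α)·ΔSWdown + ΔLWdown )      [atmospheric feedbacks]
λ = 1 / (4 ε σ Ts³)
```

λ is about 0.16 K/(W m⁻²) at 290 K and decreases with temperature. The
state used for λ and the cross terms (α, SWdown) is not dictated by the
linearisation — reference, scenario, or an average are all admissible. The
package evaluates them at the *reference* state and reports the difference
between the simulated ΔTs and the decomposition total as an explicit
residual, never absorbing it into a component: this makes the
approximation auditable, and the residual shrinks quadratically as the
perturbation shrinks (the package's tests verify the factor-4 halving
ratio). Seasonal scoping is a calendar-month mask applied before temporal
averaging. Regional summaries are area-weighted means with t-based 95%
confidence intervals across yearly regional means.

## Attribution by ridge regression with spatial blocks

The local temperature response is modelled across grid cells as
`ΔT_i = β₀ + Σ_p β_p x_ip + ε_i`, where β_p is the temperature sensitivity
to transition p in °C per unit cell fraction. Transitions co-occur and are
correlated, so coefficients are estimated by ridge regression:

* predictors are standardised on training cells only (constant predictors
  are dropped from that fit and reported);
* the intercept is free and unpenalised — it absorbs spatially uniform
  non-local effects, which is exactly where the model expects them;
* the penalty is chosen per fit from 25 log-spaced values on [0.1, 2000]
  by grouped 5-fold cross-validation over training *blocks* (the grid
  count, fold count, and the exact upper endpoint are this package's
  choices; only the endpoints' order of magnitude is externally given);
* coefficients are back-transformed to °C per unit fraction.

Uncertainty comes from 200 iterations of a **spatial block bootstrap**:
square blocks (default 5 cells per side) tile the grid; each iteration
draws 75% of blocks *with replacement* for training and evaluates on the
blocks never drawn. The 2.5th/97.5th percentiles of the 200 coefficient
estimates form the confidence interval. Drawing with replacement matters:
deviations of plain 75% subsample refits around the full-sample estimate
have standard deviation about `sqrt(1/0.75 − 1) ≈ 0.58` of the estimator's
standard error, so their percentile interval covers a true coefficient
only ~75% of the time, whereas the with-replacement block bootstrap
restores near-nominal coverage (the package's recovery tests measure
~95% over 20 seeded replicates). Blocking, rather than cell-wise
resampling, keeps spatially autocorrelated errors from leaking between
training and evaluation.

Reported contributions are the mean sensitivity times the regional signed
percentage change of each transition; reporting is restricted to
transitions occurring on >0.2% of the regional area and in >20% of cells,
with the full table always preserved. Additional spatial predictors
(coordinates, background climate) are deliberately excluded from the
default model; they improve fit scores but blur the interpretation of the
transition coefficients. The response defaults to 2 m air temperature,
with skin temperature selectable.

## Regional and extreme statistics

* **TXx** is the per-year, per-cell maximum of daily maximum 2 m
  temperature; missing days are tolerated and flagged.
* **Paired tests.** Scenario-vs-reference responses are tested per cell
  with the two-sided Wilcoxon signed-rank test on the paired yearly
  values: paired runs share boundary conditions, so pairing removes
  year-to-year variation as a confounder. All-tied cells are flagged not
  significant. When every yearly difference has the same sign, the exact
  two-sided p is `2^(1−n)` regardless of magnitude ties (the extreme of
  the tie-conditioned signed-rank distribution); the package computes this
  case directly, since a deterministic response offset would otherwise
  fall back to a normal approximation.
* **Unpaired tests** (e.g. future-vs-recent) use the two-sided
  Mann–Whitney U test.
* **FDR.** p-values are adjusted by the Benjamini–Hochberg step-up
  procedure. The family is all tested cells within one
  variable × season × scenario combination — a grouping choice this
  package fixes explicitly since finer or coarser families would also be
  defensible. Significance defaults to adjusted p < 0.05.
* **Masks and bins.** The 1% most affected cells (by PFT change fraction
  `Σ|Δf|/2`), the 1% most extreme cells of a reference field, and the 1%
  most changing cells each contain exactly `⌈0.01·n⌉` cells, with ties
  broken by cell index. Perturbation bins (0–10, 10–30, 30–50, 50–100% of
  cell area changed) are right-open except the last and partition all
  cells.

## The synthetic generator

The generator emulates the statistical structure of the real input stack,
not its geography. Its defaults define the study conditions used by the
package's tests:

* fine grid 80×80, coarsening factor 2 (a 40×40 analysis grid), 15
  analysis years, and a 91-day summer season for the daily-maximum stream;
* a thematic register of 12 land systems, 16 habitat types, 60 species,
  and 120 plots — rich enough that all transition types are linearly
  identifiable from the resulting maps (the real registers are far larger;
  a register that is too coarse makes transition predictors exactly
  collinear, and no regression could then separate them);
* 30% of fine cells change land system in the scenario;
* true sensitivities per canonical transition direction (°C per unit
  fraction, within ±3), extended antisymmetrically so that the directed
  generative model equals the signed dominant-direction regression model
  exactly;
* a spatially uniform non-local offset of 0.1 °C (its magnitude is a free
  parameter of the generator — nothing external fixes it — and the
  attribution intercept should recover it), spatial noise of 0.1 °C, and
  interannual AR(1) anomalies (ρ = 0.5, innovation sd 0.5 °C) shared
  between the paired runs, emulating runs driven by identical boundary
  conditions.

Climate fields are built backwards from the prescribed response: the mean
skin-temperature difference per cell is drawn from the linear transition
model; the flux perturbation it requires, `ΔTs/λ`, is allocated across
latent heat (35%), sensible heat (25%), albedo (15%), downwelling
shortwave (15%) and longwave (10%) by configurable weights; and ground
heat flux closes the balance exactly in both runs. This guarantees every
downstream stage an analytic expectation: closure residuals are zero to
machine precision, the decomposition reproduces the prescribed response up
to a quadratic linearisation error, and penalty-free regression on
noiseless output recovers the true sensitivities to <1% relative error.
Daily maxima are seasonal means plus Gumbel-distributed excursions
(location +8 °C, scale 2 °C), giving TXx realistic extreme behaviour.
Precipitation, soil moisture, wind, and gross primary production are
generated as independent fields with configurable scenario offsets — they
are analysis targets, not decomposition inputs, so no physical coupling is
claimed.

All randomness flows from one root seed through named substreams, so
individual outputs are reproducible in isolation and identical
configurations give bit-identical datasets.

**What passing tests do and do not show.** The generator's differences
from real model output matter for interpretation: real responses are not
exactly linear in transitions, non-local effects are not spatially
uniform, interannual variability is not a shared AR(1) process, and flux
changes are physically coupled rather than allocated by weights. Tests on
synthetic data therefore verify the *correctness of the computations* —
conservation, closure, additivity, calibration, recovery under the model's
own assumptions — not the adequacy of the linear attribution model for any
particular real experiment.

## Numerical choices and degenerate inputs

* Greedy residual tolerance 1e-12 (absolute fraction); per-cell fraction
  conservation is checked to 1e-9 before matching and violations are
  errors, not warnings.
* All-zero raw cover is a valid all-bare cell, not an error; empty land
  units carry a placeholder all-bare composition with zero area weight.
* Exact ties — habitat suitability, transition direction totals,
  most-increased/decreased categories, mask ranks — all resolve by fixed
  deterministic orders (lowest code, canonical category order, cell
  index), so results are platform-independent.
* An attribution iteration that fails is recorded and excluded; more than
  10% failures abort the analysis.
* Problem sizes used by the test suite (40×40 analysis grids, 15 years,
  200 bootstrap iterations, 20 replicate seeds, 10,000-cell calibration
  fields) are the package's chosen study conditions; they keep every
  analytic expectation testable at full precision.

## Known limitations

* The habitat stage is a crosswalk-plus-suitability stand-in; it cannot
  emulate the uncertainty of fitted habitat models.
* The attribution model is local and linear: interactions, nonlinear
  responses, and spatially structured non-local effects end up in the
  error term or the intercept.
* Gridded interchange uses flattened CSV tables; they are portable and
  diff-able but not efficient for large domains.
* The decomposition's components are not independent mechanisms — process
  coupling (e.g. radiation driving turbulent fluxes) means component bars
  describe bookkeeping of the linearised balance, not causal separation.
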