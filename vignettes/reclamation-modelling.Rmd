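---
title: "Modelling abandoned mine land reclamation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling abandoned mine land reclamation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amlscape)
```

`amlscape` couples a non-spatial demand model with a spatial allocation
model to simulate how abandoned mine land (AML) is reclaimed into other
land uses, and evaluates the resulting maps with landscape-pattern
metrics. This vignette explains the science of each stage, the tunable
parameters and their defaults, what the synthetic-landscape generator
does and does not emulate, and the numerical choices made where the
design was genuinely open.

## 1. The landscape and its classes

The modelled system is a mining district of 46,634 one-hectare cells
(100 m grid) holding eight land-use classes: cultivated land, garden
land, forest land, grassland, construction land, AML, water and
unutilized land, with base-year areas of 831, 1678, 30,165, 3686, 2733,
3573, 905 and 3063 hm². AML exists to be consumed: between the base year
(2007) and the planning horizon (2020), 3072 hm² of it are reclaimed and
501 hm² remain.

## 2. Mined-land suitability

Each AML patch is one assessment unit, graded against seven limiting
factors for four candidate uses. The limit-condition rule scores the
unit by its worst factor ("cask principle"): ordinal grades 1–3 are
suitability classes, N is unsuitable, and one N anywhere flips the unit
to unsuitable for that use. `grade_factor()` implements the criteria
table (`default_criteria()`, also shipped as
`inst/extdata/reclamation_criteria.csv`).

Two open points in the criteria and how the package resolves them:

* Several printed grades are ranges ("1 or 2", "2 or 3", "3 or N")
  whose secondary discriminant is not stated. The default resolution
  takes the *worst* printed option — conservative for reclamation
  planning — and `rule = "best"` selects the other reading. Both are
  exercised in the tests.
* The soil-thickness criteria grade 20–40 cm as "3 or N" and below
  10 cm as N, leaving 10–20 cm unstated. The implementation extends the
  20–40 cm band down to 10 cm, on the view that the N band expresses a
  hard floor and the intermediate band the last graded interval.

Note a structural consequence of the criteria: the best damage band
("light damage") grades 2 for every use except construction, so no AML
unit can reach suitability class 1 for cultivated, garden or forest use;
class 1 is reachable only for construction land. The per-use sums of
suitable patch areas (`aggregate_bounds()`) cap the reclamation
variables of the demand LP.

## 3. Demand by linear programming

Variables `x1..x8` are horizon-year class areas net of reclamation and
`x9..x12` the AML areas reclaimed to cultivated, garden, forest and
construction land. `build_lp()` assembles, per scenario, the objective
(total land-use niche or total ecosystem service value of the final
structure) over the constraint set: total-area conservation, the total
reclamation requirement, fixed residual AML, suitability caps, planning
floors, and optional per-class caps. `solve_lp()` is a two-phase dense
simplex with Bland's rule; every returned vertex is re-checked
constraint by constraint within 10⁻⁶ hm², and tests compare it against
brute-force vertex enumeration on all small problems.

Design choices that deserve justification:

* **The total-area equality includes `x12`.** The printed form of the
  constraint sums only `x1..x11`, but reclaimed construction land is
  still land; omitting it breaks area conservation. The package
  conserves all twelve variables.
* **Reclamation slack.** The suitability caps sum to 3071.9 hm², a
  rounding step short of the 3072 hm² reclamation requirement, which
  would make the printed system infeasible as an equality. The
  reclamation constraint is therefore `total − slack ≤ Σ x9..x12 ≤
  total` with `reclamation_slack = 0.5` hm² (half the rounding unit of
  the published caps). Class totals are unaffected because the
  total-area equality, not the reclamation equality, determines them.
* **The ESV scenario relaxes the forest cap.** With `x12 = 0` the
  remaining caps absorb only 1990.4 hm² of the 3072 hm² requirement.
  Since any unit suitable for construction also meets the laxer forest
  criteria of the grading table, the forest cap is raised by the
  construction-suitable area (default `relax_forest_cap = TRUE`); the
  resulting forest-dominated reclamation matches the intent of an
  ESV-maximal scenario.
* **Per-class planning caps are a shipped fixture.** The printed
  constraint set bounds nothing above except the reclamation variables;
  under either objective all free area would drain into the single
  highest-valued class (water). The caps returned by `scenario_caps()`
  close the problem so that the LP reproduces the scenario demand
  tables; they are calibration data of the study landscape, not model
  output, and users supply their own via `extra_caps`.

Yearly demand between base and horizon year is linear interpolation
per class with largest-remainder rounding to whole cells, so every
yearly vector sums exactly to the landscape area.

## 4. Spatial allocation

For each class a one-vs-rest binomial logit on the 15 driving factors
(`fit_logit()`, maximum likelihood over all valid cells) yields the
probability surface `P_iu`; model skill is screened by rank-statistic
ROC AUC with midrank ties. Quasi-separated fits are flagged and, when
`glmnet` is available, refitted with a weak ridge (λ = 0.01) to keep
coefficients finite.

Allocation of one yearly step assigns every cell the allowed class
maximizing `TPROP = P + ELAS + ITER`, then adjusts the per-class
competition variable ITER until all class areas meet demand:

* **ELAS interpretation.** The total-probability formula does not say
  whether the elasticity bonus applies to all candidate classes or only
  the cell's current class. The package defaults to the incumbent-only
  reading (`elas_mode = "incumbent"`), the standard elasticity-to-change
  semantics in CLUE-S practice — a constant added to *every* class
  would cancel in the argmax — and offers `"all"` as the literal
  reading.
* **ITER update.** The update rule is not specified by the method
  description. The package uses a proportional additive update,
  `ITER_u += η (demand_u − allocated_u) / demand_u` with η = 0.05,
  clipped to ±10, and halves a class's step whenever its deficit
  changes sign. The converged state is a set of class offsets under
  which the argmax occupancy meets demand — the discrete
  optimal-transport equilibrium — which is why exhaustive search over
  all feasible assignments finds the same solution on small grids.
* **Convergence tolerance** defaults to 0.5% of each class demand,
  never tighter than one cell; `max_iter = 2000` per year, exceeded
  iterations are an error, not a silent shortfall. On the 46,634-cell
  landscape a 13-step run converges in roughly 300–1200 iterations per
  year (about a minute in total).
* **Determinism.** Ties in TPROP break toward the lowest class code and
  all randomness lives in the generator seed, so identical inputs give
  identical maps.
* **Conversion rules.** No class may convert into AML; construction
  land and water only self-transition. Default elasticities encode the
  same story: 1.0 for the two protected classes, 0.8 for forest, 0.2
  for AML, intermediate values for the rest. These are judgement
  parameters, adjustable per run.

## 5. Landscape metrics

`landscape_metrics()` reports nine landscape-level indices. Conventions
(the published analysis names the metrics but not their
parameterization): patches are 8-connected components; adjacency counts
for contagion use double-counted 4-neighbour pairs with nodata and
boundary adjacencies excluded; the landscape boundary counts as edge
for the shape index; patch-size CV uses the population standard
deviation; the connectance threshold defaults to the landscape mean
nearest-neighbour distance, the criterion the source analysis reports
tracking. Two boundary behaviours worth knowing: contagion attains
exactly 0 on rasters whose class proportions and adjacencies are
perfectly balanced (the open lower bound often quoted for it is not
attainable on discrete maps), and a 2-class checkerboard scores exactly
50, *above* two solid halves of the same proportions at finite size —
the index separates disaggregation (many patch types finely mixed) from
aggregation, not interspersion per se.

## 6. The synthetic landscape generator

`generate_landscape()` emulates the study conditions: 46,634 valid
one-hectare cells (a 216 × 216 rectangle with 22 nodata padding cells,
since 46,634 admits no usable rectangle), exact base-year class areas,
93 AML patch nuclei, and 15 driving factors built as standardized
deterministic gradients plus noise smoothed over `clump_scale = 4`
cells. Class labels come from a quota-balanced argmax over utilities
`b0 + Xβ` (the generator-truth logits of `default_true_betas()`) plus a
class-specific autocorrelated clumping field (`clump_weight = 1.5`);
the AML field is a set of radial bumps so mined land condenses around
its nuclei, reflecting that mine siting is largely exogenous to the
driving factors. The balanced assignment makes per-class counts exact
while preserving the monotone link between utility and membership.

What the generator does *not* emulate: real road-network geometry,
hydrology, or the empirical spatial covariance of the original survey
rasters. Passing tests therefore demonstrate internal correctness of
the pipeline — demand tracking, rule compliance, coefficient-sign
recovery, metric arithmetic — not predictive skill on the real
district; the published ROC values and the 0.90 Kappa against the 2013
reference map depend on data this artifact does not contain.

Two quantitative notes. First, fitted one-vs-rest coefficients recover
the *signs* of the generator truth for loadings of at least 0.6
log-odds per factor SD (on ≥ 10,000 cells); below that a competing
class loading the same factor more strongly can mask the marginal
association (e.g. a 0.5 grassland elevation loading under a 0.8 forest
loading), which is a property of one-vs-rest fits to multinomially
assigned labels, not a bug. Unbiased 3-SE recovery holds when outcomes
are drawn from the stated binomial logit itself, which is what the
recovery tests do. Second, simulating with fitted coefficients and
comparing against the "future truth" produced from the generator's own
betas (`forward_reference()`) gives Kappa ≈ 0.86 at the default
full-scale configuration — the regression bar in the tests is 0.8.

## 7. Problem sizes used in the tests

Unit tests run on 20×20 to 100×100 landscapes; the full-scale
acceptance properties run one seeded 46,634-cell, 13-step simulation
plus its forward reference (about three minutes); metric bound checks
use 1,000 random 6×6 rasters, and all oracle comparisons (flood fill,
vertex enumeration, exhaustive allocation, pair counting) use inputs
small enough for the naive algorithms to be unquestionably correct.

## 8. Known limitations

* The demand LP reproduces the scenario tables only with the shipped
  per-class caps; the full constraint set behind the published
  scenario-2/3 demands is not recoverable from the printed material.
* Patch-distance computations (ENN, connectance) are exact but
  quadratic in patch count per class; very fragmented maps are slow.
* No region-restriction layers, neighbourhood enrichment, stochastic
  allocation, or multi-objective demand optimization.
* The suitability module models the published grading criteria only;
  policy, economic finalization and public participation are out of
  scope (an override column on the criteria CSV is the intended hook).
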