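---
title: "Interpolating built-settlement growth and mapping population with random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpolating built-settlement growth and mapping population with random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gridded population surfaces are the denominator of much of spatial
epidemiology: rates, coverage estimates, and catchment populations all rely
on knowing how many people live in each pixel. Census counts, however, are
only available as totals over subnational units, and only for some years.
Top-down population modelling closes the gap by *disaggregating* the unit
totals over pixels using ancillary covariates — most importantly, where the
built settlement (BS) actually is. But settlement maps themselves exist only
at a few observed epochs, so an annual population series needs annual
settlement extents that nobody observed.

`bsgmpop` implements the full chain that addresses this:

1. **BSGMi** — an interpolative built-settlement growth model that produces
   annual BS extents between two observed epochs;
2. **RF dasymetric disaggregation** — a random-forest-informed weighting
   scheme that converts unit population counts into pixel-level counts;
3. **WIR meta-analysis** — a rank-based analysis of covariate importance
   across many country- and year-specific models;
4. a **synthetic scenario generator** with known ground truth, so every
   stage can be validated end to end without any external data.

## BSGMi: demand quantification and spatial allocation

BSGMi splits interpolation into *how many* pixels transition from non-BS to
BS in each unit and year (demand), and *which* pixels (allocation).

**Demand.** For each unit, the BS population observed coincident with the
epoch extents is interpolated with a unit-specific logistic growth curve,
and BS population density (BS population per BS pixel) with a natural cubic
spline. A three-parameter logistic cannot be identified from two
observations, so with two epochs the carrying capacity must be supplied; we
default to twice the larger endpoint, and we also keep the historical
two-point exponential variant (`v(t) = v0 e^{rt}`) that earlier production
runs used — the two variants differ in when transitions happen (the
exponential form back-loads them), which is itself a tested property.

The interpolated series imply an annual BS area `A_t = population_t /
density_t`. The per-year demand weight is `w_t ∝ max(0, A_t − A_{t−1})`:
the published description derives weights from "relative changes" of the
two interpolated series without printing a formula, and the implied-area
construction is our declared surrogate — it uses both series, reproduces
every stated property (nonnegative, normalised, anchored at the epochs),
and degrades gracefully (uniform weights) when a unit shows no growth.
Negative increments are clamped: an interpolative model cannot remove
settlement. The unit's observed period transition count is then apportioned
to years by largest remainder, which conserves the integer total exactly
and minimises the deviation from the real-valued quotas.

**Allocation.** A 500-tree classification random forest is trained on all
pixels that transitioned over the period plus an equal-size seeded sample
of persistent non-BS pixels (class balance; the training design is not
specified in the source descriptions, so it is declared here). Predictors
are the epoch-t0 settlement geography: distance to the nearest BS edge
(DTE), the proportion of BS within 1/5/10/15-pixel Euclidean discs,
elevation, slope, and distance to the protected-area analogue. The
forest's vote fraction is the period-level transition probability; each
year it is multiplied by a lights-at-night (LAN) weight — the annual
radiance difference, min-max rescaled within each unit to [0, 1] — and the
unit's demand is placed on the top-`k` remaining candidates. Because
candidates are restricted to pixels that actually transitioned over the
period, the series is monotone and agrees bitwise with both observed
epochs. Ties are broken by a seeded shuffle: reproducible, but unbiased
among equal-probability pixels. If integer apportionment ever asks a unit
for more pixels than remain, the shortfall carries to the next year, which
preserves the global accounting.

## Dasymetric population disaggregation

Each year's model is trained at the unit level: the response is the natural
log of population density (count over land pixels) and the predictors are
unit means of the year's covariate stack — the year-specific BS DTE
(interpolated extents for interim years, observed ones at the epochs), the
historical epoch-t0 BS DTE, the DTE of the coarse annual settlement
product, LAN, and the static layers. The log transform is a design choice
(the production framework this follows predicts density on a stabilised
scale); because predictions are used only as *unit-relative weights*, any
monotone rescaling of the response cancels in the renormalisation.

Fitting uses 500 trees with `mtry` tuned by a seeded out-of-bag search
(start at `p/3`, double or halve while OOB MSE improves by more than 5%),
and iterative covariate elimination: refit and drop every covariate whose
permutation importance is ≤ 0 until none is dropped, with a floor of three
retained covariates. Permutation importance (`Per.Inc.MSE`) is computed per
tree on its out-of-bag samples, averaged, and expressed as a percentage of
the model's OOB MSE — an unscaled definition that keeps the "≤ 0 ⇒
uninformative" rule meaningful (the variance-scaled variant is undefined
for zero-variance importances). The three settlement representations are
exempt from elimination by default, mirroring production models where the
historical settlement covariate was always included from 2001 onward and
ensuring every model can contribute to the settlement contrasts.

Pixel predictions are back-transformed and renormalised within units, so
each unit's pixel values sum to its count to within floating-point
(relative error below 1e−9 is asserted in the tests). A unit with an
all-zero weight surface falls back to a uniform spread rather than
dropping its population.

## The WIR meta-analysis

Permutation importance is model-specific: magnitudes are not comparable
across models with different covariate sets. The Weighted Importance Rank
divides a covariate's within-model rank (descending importance, ties
averaged) by the number of covariates in the model:

`WIR = rank / n_covariates ∈ (0, 1]`

Lower is more important; the least important covariate scores exactly 1 and
the most important `1/n`. We implement the ratio literally: prose
descriptions sometimes round the best case to "0", but `1/n` is what the
definition yields and the two agree as `n` grows. WIR is invariant under
monotone transforms of the raw importances, which is the point: it survives
the importance "stealing" that correlated covariates inflict on magnitudes.

Distributional comparisons use the tie-corrected Kruskal–Wallis test
(chi-square reference, `k − 1` degrees of freedom), Dunn's pairwise
mean-rank z tests with Holm step-down correction, and one-sample Wilcoxon
signed-rank tests of WIR differences against a zero median with Holm
correction across contrasts and regions. The source analysis calls the
latter a "one-sample Wilcoxon rank sum test"; the only one-sample Wilcoxon
test of a median is the signed-rank test, which is what we implement. For
n ≤ 25 the signed-rank null is computed exactly (dynamic programming over
the tied-rank multiset, equivalent to enumerating all 2^n sign
assignments); larger samples use the normal approximation with tie and
continuity corrections. Dunn tests always run but are flagged as
interpretable only when the omnibus test is significant. Boxplot summaries
use type-7 quartiles (linear interpolation) and 1.5×IQR whiskers clamped to
the data range, so summaries are reproducible bit for bit.

## The synthetic scenario generator

The generator emulates the statistical structure of the real inputs on a
planar lattice with unit pixel spacing — distances only ever enter in pixel
units, so projections are irrelevant and deliberately out of scope.

* **Landscape.** Water is the lower tail of a smooth random field
  (default 8% of the grid); land is partitioned into contiguous units by
  flood fill from farthest-point seeds; elevation is a smooth field, slope
  its gradient magnitude; roads are random straight lines and the
  protected area a random disc, both entering as distance fields.
* **Settlement.** One compact radius-2 disc per unit seeds the t0 extent at
  the most road-accessible pixel (13 pixels — large enough that the coarse
  3×3 majority product cannot lose it entirely). Each year the number of
  transitions is Binomial(candidates, `growth_rate`) — so the expected
  per-year transition fraction equals `growth_rate` exactly — and pixels
  are selected by weighted sampling, with weights decaying in distance to
  existing settlement and modulated by a smooth static suitability field.
  The suitability field gives units genuinely different growth
  trajectories, which is what makes an annual settlement covariate
  informative beyond the epoch-t0 one.
* **Coarse annual product.** Block majority vote (ties vote 0) at
  `coarse_factor` = 3, then nearest-neighbour upsampling: a 300 m-style
  annual product on a 100 m-style grid.
* **LAN.** `baseline + gain × local BS density (radius-3 disc) + N(0, sd)`,
  truncated at zero.
* **Population.** Pixel log density is
  `alpha + settlement_effect · exp(−DTE/proximity_scale) + Σ γ_k z_k +
  noise`; unit counts are the rounded pixel-density sums; water holds no
  population. The BS population series handed to demand quantification is
  the same (noise-free) density summed over each year's true extents — the
  population "coincident with" the extents. Only its two epoch rows are
  visible to the models.

Defaults (64×64 grid, 4 units, 13 annual steps, `growth_rate` 0.05,
`settlement_effect` 3, `noise_sd` 0.3) describe the reference scenario used
to score interpolation skill. The noise model is a stated assumption: the
variance structure of real interpolated census counts is not characterised
in the sources, so nothing here should be read as inference about it.

What the generator does *not* emulate: realistic urban morphology (growth
is proximity plus a smooth field, not streets and zoning), geodesic
geometry, sensor artefacts in the lights data, census revision error, or
multi-country border effects. Passing tests demonstrate that the
implementation recovers known mechanisms under its own generating
assumptions — not that those assumptions describe any particular country.

## Validation design and problem sizes

The test suite pairs every nontrivial numeric path with an independent
oracle: the distance transform against an all-pairs search (exact
equality), disc proportions against enumeration, top-k allocation against
exhaustive subset search, largest-remainder apportionment against the
enumerated optimum, the exact signed-rank p against full sign enumeration,
and Kruskal–Wallis against a from-first-principles computation.
Interpolation skill is scored on 64×64, 4-unit, 13-year scenarios (3
seeds): median interim-year pixel accuracy is required to reach 80%.
Mechanism recovery uses 48×48, 60-unit, 13-year scenarios with
settlement-dominated density (`settlement_effect` 6, `noise_sd` 0.05,
static effects near zero) over 20 replicates: the annually interpolated
settlement covariate must out-rank the static epoch-2000 one in at least
80% of replicates. Covariate elimination is validated on synthetic unit
tables: informative covariates must always survive, and a designated
pure-noise covariate must be removed in a clear majority of replicates.
The removal rate deserves a caveat: the permutation importance of a
covariate truly independent of the response fluctuates almost
symmetrically around zero, so a "drop if ≤ 0" screen catches it on
roughly a coin flip per fit; iterative re-testing raises the observed
removal rate to about 70–85% depending on the table, but no faithful
configuration of the rule makes removal near-certain. Users should read
retention of a weak covariate as "not ruled out", not as evidence of
signal. These sizes keep a full run at desk scale
while leaving each check enough replicates to be stable; they are the
package's reference conditions, stated here so results are interpretable.

## Numerical and degenerate-input choices

* DTE is unsigned (0 inside the class); the signed-inside variant adds no
  ordering information outside the class, which is all the forests see.
* An empty mask has no defined distance and raises an error — this is the
  "unit with no settlement" signal, not a value.
* A unit whose LAN difference is constant gets weight 0.5 everywhere:
  an uninformative year should neither veto nor guarantee transitions.
* Largest-remainder ties go to the earlier year; top-k ties are broken by
  seeded shuffle.
* Proportion-in-radius discs are Euclidean (center included) and truncated
  at the grid edge, so edge values remain proportions of real pixels.
* Non-finite permutation importances (possible on very small unit tables,
  where a covariate may acquire no usable out-of-bag evidence) are treated
  as zero importance.
* All generators draw from per-operation sub-streams derived from one
  master seed, so regenerating one layer never perturbs another.

## Limitations

WIR only captures rank at the model's level of representation; it cannot
see subnational variation in covariate contribution, and alternatives
(accumulated local effects, Shapley values) are out of scope here. The
logistic/spline demand model is a surrogate for an incompletely published
weighting formula and should be treated as such. The allocation contract
is correctness at desk scale — continental rasters would need tiling and
parallelism that this package intentionally does not attempt.
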