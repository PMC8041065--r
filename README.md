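# bsgmpop

Annual built-settlement growth interpolation, random-forest dasymetric
population mapping, and rank-based meta-analysis of covariate importance —
with a synthetic-scenario generator so the whole chain can be validated
against known ground truth.

## The problem

Gridded population surfaces underpin spatial epidemiology: incidence rates,
intervention coverage, and denominator populations all need people counts
per pixel. Census data, however, arrive as totals over subnational units,
and settlement maps — the strongest predictor of where people are — exist
only for a few observed epochs. `bsgmpop` implements a three-stage chain
that closes both gaps:

1. **BSGMi (built-settlement growth model, interpolative).** Given binary
   settlement extents at two epochs t0 and t1 and the population coincident
   with them, interpolate annual extents. *Demand quantification* fits a
   unit-specific logistic growth curve to BS population and a natural cubic
   spline to BS population density, converts increments of the implied BS
   area A_t = pop_t / density_t into per-year weights, and apportions each
   unit's observed transition count by largest remainder. *Spatial
   allocation* trains a 500-tree random forest on the pixels that
   transitioned over the period, multiplies its probabilities by
   lights-at-night difference weights (min-max rescaled within units), and
   transitions the top-demand candidate pixels per unit-year. Transitions
   can only be placed on pixels observed to have transitioned, so the
   series matches both epochs exactly and is monotone.

2. **Dasymetric population disaggregation.** One 500-tree regression forest
   per country-year, trained at the unit level on log population density
   with tuned `mtry` and iterative covariate elimination (drop any covariate
   whose out-of-bag permutation importance, `Per.Inc.MSE`, is ≤ 0), then
   used to predict pixel weights so each unit's count is spread over its
   pixels: `pop(pixel) = count_unit × w / Σ w`, conserving unit totals
   exactly.

3. **WIR meta-analysis.** Importances are only rank-comparable across
   models, so each covariate gets a Weighted Importance Rank,
   `WIR = rank / n_covariates` (descending importance, ties averaged;
   least important = 1, most important = 1/n). WIR distributions are
   compared with Kruskal–Wallis tests, Dunn post hoc tests (Holm
   corrected), and one-sample Wilcoxon signed-rank tests of WIR differences
   against a zero median (exact null for n ≤ 25).

All rasters are plain matrices on a planar unit-spaced grid; raster I/O
uses ESRI ASCII grids, tables are CSV, configurations YAML.

## Worked example

Simulate a country with 30 units over 2000–2006 where density is driven by
settlement proximity, interpolate the extents from the two epochs alone,
and fit one year's population model:

```r
library(bsgmpop)

cfg <- scenario_config(rows = 48, cols = 48, n_units = 30, years = 2000:2006,
                       seed = 11, growth_rate = 0.06, settlement_effect = 5,
                       noise_sd = 0.1,
                       static_effects = c(elevation = -0.05, slope = 0,
                                          water_dst = 0, road_dst = -0.05,
                                          protected_dst = 0))
scn <- simulate_scenario(cfg)

series <- run_bsgmi(scn$bundle, n_trees = 500, seed = 11)
round(100 * bsgmi_accuracy(series, scn$truth), 1)
#> 2001 2002 2003 2004 2005
#> 95.0 90.7 88.6 89.4 93.3

pm <- disaggregate_population(scn$bundle, series[["2003"]], 2003,
                              n_trees = 500, seed = 11)
wir <- compute_wir(pm$importances)
wir[order(wir$wir), c("covariate", "per_inc_mse", "wir")]
#>      covariate per_inc_mse       wir
#>            lan 472.3903582 0.1666667
#>  bs_dte_coarse  60.1383803 0.3333333
#>  bs_dte_annual  17.2903295 0.5000000
#>      bs_dte_t0  12.7818920 0.6666667
#>       road_dst   4.3262522 0.8333333
#>      elevation   0.5012007 1.0000000
```

The accuracy row is the fraction of pixels whose settled/unsettled state
matches the withheld truth in each interim year — the interpolation is
weakest mid-period, where the least is known. In the importance table,
lights-at-night ranks first and the annually interpolated settlement
covariate (`bs_dte_annual`) outranks the static epoch-2000 one
(`bs_dte_t0`), the qualitative pattern the meta-analysis quantifies across
many countries and years. Pixel populations sum back to the unit census
counts exactly.

`run_experiment()` scales this to many countries × years, collects all
importance records, and writes WIR tables, test results, boxplot summaries
and a checksummed manifest; `inst/scripts/run-experiment.R` is a shell
wrapper around it.

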