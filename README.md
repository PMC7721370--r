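# landpop

Malthusian and Boserupian system-dynamics models of population, technology
and land use for a rural region.

## What it does

For a fixed 127,070 ha (1,271 km²) alpine region, `landpop` simulates the
coupled annual dynamics of population (three cohorts), a two-sector labour
force, five land classes, cattle and pig stocks, and an open-economy income
account over 1961–2011.  Two model variants encode opposing theories of
agrarian change:

* **M-model (Malthusian)** — technology is exogenous: yields grow by a fixed
  amount each year (the 50-year mean annual increment), and rising income
  raises fertility and lowers mortality;
* **B-model (Boserupian)** — population density drives the adoption of
  technology, proxied by the national ratio of non-agricultural to
  agricultural income; adopted technology raises yields and deepens the
  decline of fertility.

Two out-migration scenarios complete a four-run comparison matrix:
**LE** ("low earnings", emigration falls as regional income rises) and
**SC** ("structural change", emigration rises with the shift of labour out
of agriculture).

Every behavioural linkage uses one device: relative deltas from the 1961
base year, Δx = (x_t − x₀)/x₀, linear responses g fitted on deltas, applied
as y_t = x₀·(1 + g(Δx)), so forward and backward development are both
admissible.  Land accounting conserves total area exactly, and succession is
irreversible: 1/30 of the intermediate (temporarily uncultivated) area
converts to forest each year and forest can never be re-cultivated.

Because the original national and regional input series are not
distributable, a seeded generator produces synthetic drivers with their
qualitative structure (trending noisy yields, a rising-then-flattening
technology index, a mid-1960s fertility peak, declining mortality), plus a
pseudo-empirical regional series for the evaluation stage.  An evaluation
module reproduces the period-wise comparison protocol (1960–80, 1980–2000,
2000–2010) with signed endpoint deviations per variable and run.

The package is aimed at land-system and socio-ecological modellers who want
a compact, fully testable implementation of the two theories' structural
signatures — convex population growth under M versus flattening under B —
rather than a calibrated reconstruction of any particular region.

## Worked example

```r
library(landpop)

params  <- generator_params(seed = 1)
drivers <- generate_drivers(params)
init    <- generate_region_init(params)
drivers
#> synthetic driver set: 51 years (1961-2011), seed 1
#>   technology index 1.28 -> 2.82
init
#> region init: 90,000 inhabitants, 127,070 ha (95% forest+grassland)

mx <- run_matrix(drivers, init, run_config(seed = 1))
mx
#> simulation matrix: M_LE, B_LE, M_SC, B_SC
#>   M-LE: final population 234,416
#>   B-LE: final population 87,964
#>   M-SC: final population 197,243
#>   B-SC: final population 61,940

summary(mx$B_LE)
#> B-model / LE, 1961-2011
#>   population: 90,000 -> 87,964
#>   final cohorts: 14,612 children, 52,462 adults, 20,890 retirees
#>   final land shares: forest 58.3%, cropland 7.1%, grassland 32.9%
#>   mean out-migration rate: 0.58%/yr

report <- period_summary(mx, generate_empirical(params))
subset(as.data.frame(report),
       variable == "population_total" & period == "2000-2010")
#>            variable variant scenario    period year deviation_pct        verdict
#> 3  population_total       M       LE 2000-2010 2010   153.5588863 notable misfit
#> 24 population_total       B       LE 2000-2010 2010    -0.9285781       good fit
#> 45 population_total       M       SC 2000-2010 2010   115.3077328 notable misfit
#> 66 population_total       B       SC 2000-2010 2010   -29.2828585 notable misfit
```

The numbers show the theories' curvature contrast on the default synthetic
conditions: both M-runs overshoot the pseudo-empirical 2010 population by
more than 100% (sustained convex growth), while the B-model's
density-damped technology and fertility feedback flatten its trajectories —
B-LE ends within 1% of the pseudo-empirical record, and in both B-runs the
number of children falls below the number of retirees (an ageing society).
`plot(mx$B_LE)` draws the population and land-share panels.

A thin command-line wrapper with `generate-drivers`, `run` and `evaluate`
subcommands is installed under `inst/scripts/landpop-cli.R`.

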