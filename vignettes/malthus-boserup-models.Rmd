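---
title: "Two system-dynamics models of population, technology and land use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two system-dynamics models of population, technology and land use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landpop)
```

## The problem

How far do the classical theories of agrarian change — Malthus's exogenous,
arithmetically growing technology and Boserup's population-induced
intensification — still describe the coupled population and land-use
trajectory of a rural region in an industrial society?  `landpop` implements
two reduced-complexity system-dynamics models of a fixed 127,070 ha alpine
region over the 50-year horizon 1961–2011, sharing one architecture
(population, land, technology, livestock, two-sector economy) and differing
only in where technological progress comes from and what it feeds back on.
Comparing their four scenario trajectories with a regional record turns the
theoretical disagreement into testable differences in curvature: sustained
convex population growth under the Malthusian closure versus flattening under
the Boserupian one.

## The response-function device

Every behavioural linkage uses one device.  A driver $x_t$ is reduced to its
relative deviation from the 1961 base year,

$$\Delta x = \frac{x_t - x_{t=0}}{x_{t=0}},$$

a linear response $g$ is fitted (or configured) on such deltas, and applied
multiplicatively,

$$y_t = x_{t=0}\,\bigl(1 + g(\Delta x)\bigr).$$

Because deltas are signed, the same line models forward ($g > 0$) and
backward ($g < 0$) development; results that would turn physically
meaningless quantities negative are floored at zero with a warning.  Fits are
ordinary least squares (`fit_response()`, one covariate per linkage — the
simplest reading of a linear-regression calibration; multivariate and
non-linear forms are out of scope).

## Demography

Population is carried as three aggregate cohorts — children (< 15), adults
(15–65), retirees (> 65).  The cohorts are stocks, not single-year ages, so
ageing uses the uniform-age approximation implied by the cohort widths: 1/15
of children and 1/50 of adults move up each year.  Gender is split equally
and the female half of the adults reproduces over a 30-year cycle, giving
annual births $f \cdot (\text{adults}/2)/30$.  Out-migration removes adults
only, and emigrants do not return.  The bookkeeping identity
$\Delta\text{total} = \text{births} - \text{deaths} - \text{emigrants}$
holds exactly at every step and is re-validated on every assembled
trajectory.

**Fertility decomposition.** The observed total fertility rate of an
industrial country rises to a mid-1960s peak and then declines, which no
purely income-driven mechanism can produce.  `split_fertility()` therefore
decomposes the actual series into a linearly increasing "Malthusian" term —
the affine extension of the line through the first two observations — and a
residual (actual − Malthusian), negative once the decline sets in.  The
reconstruction identity holds to double precision by construction.  The
Malthusian variant uses only the increasing term, raised further by lagged
income (`m_fertility()`); the Boserupian variant inherits both terms, with
the *negative part* of the residual deepened by the technology delta
(`b_fertility()`).  Restricting the deepening to the negative part is a
deliberate choice: it guarantees that raising the technology index can lower
but never raise Boserupian fertility even in early years where the residual
briefly sits above zero, and leaves the reconstruction intact at zero
technology delta.  How strongly income lifts the Malthusian term and
technology deepens the residual is nowhere quantified empirically; the
defaults (+0.1 income slope, +0.3 deepening) were chosen once as moderate
values producing the expected curvature contrast and are ordinary config
entries.

**Migration scenarios.** LE ("low earnings"): the rate responds negatively
to the relative delta of lagged regional income per adult,
$\text{rate} = \mathrm{clip}\bigl(r_0 (1 + g(\Delta\text{inc})), 0, 1\bigr)$
with $r_0 = 0.04$ and slope −1.5, so emigration starts near 4%/yr and
recedes as incomes grow.  SC ("structural change"): the rate responds
positively (slope +3, base 1%/yr) to the relative decline of the
agricultural labour share, so it grows as technology pulls labour out of
agriculture.  Sign contracts are enforced at construction.

## Technology closures

**M-model.** Yields per land type grow by a fixed annual increment — the
50-year mean annual growth of the national series, read as the endpoint mean
$(y_T - y_0)/T$ rather than the OLS slope, matching an "average yearly
increase" framing; both are exposed by `compute_delta_from_series()`.
Regional yields are therefore exactly affine in time (zero second
difference), the operational meaning of arithmetical growth.  Income effects
close the Malthusian loop: lagged income raises fertility (slope +0.1) and
lowers mortality (slope −0.2).

**B-model.** The technology on offer is proxied by a national index, the
ratio of non-agricultural to agricultural income.  Regional population
density governs adoption, linearly in density relative to 1961 and capped at
1: $a = \mathrm{clip}(a_0\,\rho/\rho_0, 0, 1)$ with $a_0 = 0.5$ — the paper
behind this design states only the sign of the density effect, so the anchor
value and linear form are the simplest monotone choice.  The density
denominator is the constant total region area (1,270.7 km²).  Adopted
technology scales yield responses fitted on national deltas:
$y = y_0 (1 + a \cdot g_{\text{tech}}(\Delta\text{index}))$, one response per
land type, fitted by the engine from the supplied drivers at setup.  Whether
the harvest response should read the index level or its delta is not
explicit in the source material; the delta form is used for symmetry with
the general device.  The behavioural technology covariate for labour, land
preference, capacity, milk and wood responses is the index delta in the
B-model and the mean relative yield delta in the M-model (where the index
plays no causal role).

## Land use

Five classes: crops, fodder crops, grassland (the cultivated area),
intermediate area, forest.  "Fallow" is identified with the intermediate
area.  Cultivation each year is farmers × capacity, where capacity is the
minimum of available agricultural land per farmer and the 1961 capacity
augmented by technology; the split shifts toward crops and away from
grassland as technology rises (share re-weighting with a +0.8 preference
slope, fodder scaled alongside crops, grassland absorbing the complement).
Within a step, re-cultivation/abandonment transfers run first, then 1/30 of
the *post-transfer* intermediate stock succeeds irreversibly to forest —
this ordering keeps abandoned land re-cultivable "next year" as intended.
With recultivation at zero the intermediate pool therefore decays as
$(29/30)^t$.  Areas are continuous hectares with an exact conservation guard
(drift beyond $10^{-6}$ relative is an error; anything smaller is parked in
the intermediate pool), and the realized flow matrix is attached to every
step so the absence of any forest-outflow pathway can be audited
structurally, not just numerically.

## Livestock and the economy

Cattle are bound to grassland and pigs to fodder cropland through
stocking-density caps (default 2 head/ha each — the legal limits are cited
but not quantified in the source, so the caps are config).  Stocks evolve as
$\min(s(1 + \text{fert} - \text{slaughter}), \kappa \cdot \text{land})$.
Half the cattle are dairy; milk per cow responds to the grass:fodder harvest
ratio through the saturating anchor-normalized factor $h(r) = 2r/(r + r_0)$
(monotone, $h(r_0) = 1$, bounded below 2) and to technology.  Beef and pork
are slaughtered head × carcass mass (0.25 t and 0.09 t).  Wood output is
forestry workers × base productivity × technology response; forestry labour
is a fixed 10% of agricultural labour, a configurable stand-in for an
allocation the source never specifies.  The income account is an exact dot
product over the five monetized products (crops, milk, beef, pork, wood) at
exogenous world-market prices; fodder and grass harvests are feed and carry
no revenue.  Industrial income is exogenous; regional income per adult mixes
the two sectors by the labour split.

## Engine ordering and lags

Within a year the update order is fixed: drivers → technology → demography →
labour → land → livestock → production/income → record.  The variants'
causal orderings are realized through what feeds what: B-model adoption uses
the *previous* year's population density (population precedes technology),
and all income responses (fertility, mortality, LE migration) use the
previous year's income, avoiding within-year simultaneity.  The simulation
step itself is deterministic given the drivers; all randomness lives in the
generator.  Degenerate inputs are handled without special modes: a frozen
driver set falls back to the trivial fertility decomposition and zero
response fits, zero farmers yield zero cultivation for that year, and a zero
agricultural labour force reports per-worker income as missing.

## The synthetic driver generator

The study's national and regional input series are not distributable, so the
generator emits seeded synthetic stand-ins with their qualitative structure:

* yields: linear trends with Gaussian noise (crop 2.9 t/ha + 0.055/yr,
  sd 0.12; fodder 6.0 + 0.09; grass 4.8 + 0.03); the crop base is the
  area-weighted reference over four representative cultures;
* prices: mild drifts with 2% lognormal noise, in one synthetic currency;
* incomes: industrial income grows 4%/yr; the technology index follows the
  saturating shape $r_0(1 + 1.25(1 - e^{-t/20}))$ from about 1.3 to about
  2.8 — rising then flattening — and agricultural income is derived as
  industrial/index;
* fertility: 2.78 in 1961, peak 2.82 in 1963, exponential relaxation toward
  1.4 (Austrian-like levels); mortality declining 0.8%/yr; emigration
  decade-wise constant around 0.8%/yr;
* region: 90,000 inhabitants (the empirical order of magnitude) with
  1961-like cohort shares, land shares summing to 127,070 ha with forest
  (55%) + grassland (40%) = 95%, 30,000 cattle, 4,000 pigs, a quarter of
  adults in agriculture.

A pseudo-empirical regional series (population growing ~3% to 1980 then
oscillating around 90,000; children falling, retirees rising; forest share
creeping up, grassland declining) exercises the evaluation stage and is
labelled synthetic everywhere.  What the generator does **not** emulate:
policy structural breaks (agri-environmental programmes, EU accession),
price shocks, the spatial pattern of the region, or any calibration to the
real Austrian series.  Passing tests on this synthetic world demonstrate
internal consistency and the theories' qualitative signatures, not
empirical validity for the real region.

## Evaluation protocol

The horizon splits into 1960–80, 1980–2000 and 2000–2010.  For each run,
variable and period the report gives the signed endpoint deviation
$100(\text{model} - \text{empirical})/\text{empirical}$ at the last year
both series share in the period (which also absorbs excluded trailing data
points).  The metric is antisymmetric in sign but not magnitude — a 2×
inflation reads +100%, the matching 0.5× deflation −50% — which is
documented and tested rather than corrected.  Verdict labels use heuristic
cutoffs (|dev| ≤ 5% good, ≤ 20% moderate) and are configurable; no formal
goodness-of-fit statistic is implied.  The default variable set is total
population, the three cohorts, and the forest, cropland (crops + fodder
subsumed) and grassland shares.

## Numerical and testing choices

Problem sizes are modest by design: 51 annual records × 4 runs, so the full
matrix runs in well under a second and the whole test suite in seconds.
Exact identities (area conservation, fertility reconstruction, population
bookkeeping, zero second differences of M-yields) are asserted at double
precision ($10^{-12}$ absolute, or $10^{-6}$ ha on 127,070 ha).  The cohort
step is cross-checked against an independently coded Leslie-style matrix
projection over 30 years at $10^{-9}$ relative.  Response-fit recovery is
checked on simulated delta pairs with known slope 0.5 across 20 fixed seeds;
since a 3-standard-error bound is exceeded by chance in roughly 0.4% of
fits, the check requires at most one exceedance in 20 plus a pooled estimate
within 3 standard errors of its mean, rather than pretending every draw must
land inside.  Curvature contrasts are read from decade-wise OLS trends of
total population (first vs last decade for convexity, mid vs last for
flattening), which is robust to the driver noise that year-wise second
differences inherit.

## Known limitations

Cohorts have no age resolution, so ageing waves are smoothed; migration is
one-way and adult-only; technology is a single national scalar; land
allocation is aspatial; prices carry no inflation or policy structure; the
fertility device ties the Malthusian term to the first two observations,
making it sensitive to their noise; and none of the parameters is calibrated
to the real region — the package reproduces the *comparison protocol* and
the theories' structural signatures, not the historical record.
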