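# The two technology closures.
#
# Malthusian variant: technological progress is exogenous and yields rise by
# a fixed amount each year (arithmetical growth), the amount being the
# long-term mean annual increment of the national series.
#
# Boserupian variant: a national technology index -- the ratio of
# non-agricultural to agricultural income -- proxies the technology on offer;
# regional population density governs the rate at which it is adopted, and
# the adopted fraction of the index-driven response raises yields.

#' Fixed annual yield increments from a national series
#'
#' The Malthusian increment per land type is the 50-year mean annual growth,
#' read as the endpoint mean `(y_T - y_0) / T`.  The OLS slope over the
#' series is also returned for comparison.
#'
#' @param series Numeric national yield series covering the full horizon.
#' @param years Calendar years of the series.
#' @return List with `delta` (t/ha/yr, endpoint mean) and `ols_slope`.
#' @export
compute_delta_from_series <- function(series, years = seq_along(series)) {
  n <- length(series)
  stopifnot(n >= 2, length(years) == n)
  if (!is.finite(series[1L]) || !is.finite(series[n]))
    stopf("series endpoints are required to compute the mean increment")
  span <- years[n] - years[1L]
  list(delta = (series[n] - series[1L]) / span,
       ols_slope = unname(stats::coef(stats::lm(series ~ years))[2L]))
}

#' One Malthusian yield step
#'
#' `yield(t+1) = yield(t) + delta`, per land type; yields are therefore
#' exactly affine in time.
#'
#' @param yields Named per-type yields (t/ha).
#' @param deltas Named per-type fixed increments (t/ha/yr); names must match.
#' @return Updated yields, floored at 0.
#' @export
m_yield_step <- function(yields, deltas) {
  stopifnot(all(names(yields) %in% names(deltas)))
  pmax(yields + deltas[names(yields)], 0)
}

#' Technology index
#'
#' Ratio of non-agricultural to agricultural income per worker (national).
#'
#' @param non_ag_income,ag_income Sectoral incomes; `ag_income` must be > 0.
#' @return Dimensionless index.
#' @export
tech_index <- function(non_ag_income, ag_income) {
  if (any(ag_income <= 0)) stopf("agricultural income must be > 0")
  non_ag_income / ag_income
}

#' Density-dependent adoption rate
#'
#' Adoption is linear in population density relative to the base-year
#' density, anchored at `a_0` and capped at 1:
#' `clip(a_0 * density / density_0, 0, 1)`.
#'
#' @param density Population density (persons/km2).
#' @param a_0 Adoption rate at the base-year density.
#' @param density_0 Base-year density (persons/km2).
#' @return Adoption fraction in \[0, 1\].
#' @export
adoption_rate <- function(density, a_0, density_0) {
  stopifnot(density >= 0, a_0 >= 0, a_0 <= 1, density_0 > 0)
  clip(a_0 * density / density_0, 0, 1)
}

#' Boserupian yield response
#'
#' The adopted fraction of the index-driven response raises (or, under
#' backward development, lowers) the base-year yield:
#' `yield = yield_0 * (1 + adoption * g_tech(tech_delta))`, floored at 0.
#'
#' @param yield_0 Base-year yield (t/ha).
#' @param g_tech A [response_function()] fitted on national yield deltas
#'   against technology-index deltas.
#' @param tech_delta Relative delta of the technology index.
#' @param adoption Adoption fraction in \[0, 1\].
#' @return Yield (t/ha).
#' @export
b_yield <- function(yield_0, g_tech, tech_delta, adoption) {
  stopifnot(adoption >= 0, adoption <= 1,
            inherits(g_tech, "response_function"))
  floor0(yield_0 * (1 + adoption * predict(g_tech, tech_delta)), "yield")
}
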