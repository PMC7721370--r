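# Run configuration.
#
# One object bundles the variant (M or B), the migration scenario (LE or SC),
# the horizon, and the per-module parameter blocks.  All behavioural slopes
# live here; the engine fits the yield-vs-index response functions of the
# B-model from the supplied drivers at setup.

#' Configuration for one simulation run
#'
#' @param variant `"M"` (Malthusian: exogenous fixed annual yield increments,
#'   income raises fertility and lowers mortality) or `"B"` (Boserupian:
#'   density-dependent adoption of index-driven technology, which raises
#'   yields and depresses fertility).
#' @param scenario `"LE"` (out-migration falls with regional income) or
#'   `"SC"` (out-migration rises with the shift of labour out of
#'   agriculture).
#' @param start_year,end_year Simulation horizon (default 1961-2011,
#'   50 annual steps).
#' @param seed Integer echoed into run metadata; the simulation step itself
#'   is deterministic given the drivers.
#' @param demography,technology,land,production Parameter blocks; any entry
#'   supplied overrides the default of the same name.  See Details.
#' @param ageing Apply cohort ageing transfers (disabled only for degenerate
#'   equilibrium analyses).
#'
#' @details Block entries and defaults:
#' * `demography`: `g_labour` (labour-saving response, slope -0.3),
#'   `g_fert_income` (M-model income on the Malthusian fertility term,
#'   slope +0.1),
#'   `g_mort_income` (M-model income on mortality, slope -0.2),
#'   `fert_tech_slope` (+0.3; B-model deepening of the negative residual
#'   fertility term by the technology delta),
#'   `le_base_rate` 0.04 and `le_slope` -1.5, `sc_base_rate` 0.01 and
#'   `sc_slope` +3 (scenario migration responses).
#' * `technology`: `a_0` 0.5 (adoption at base-year density).
#' * `land`: `g_cap` (capacity response, slope +0.5), `g_pref` (crop
#'   preference response, slope +0.8), `succession_rate` 1/30.
#' * `production`: cattle fertility/slaughter 0.35/0.33, pig 0.80/0.78,
#'   stocking caps `kappa_cattle`/`kappa_pigs` 2 head/ha, `base_milk` 2.7
#'   t/cow/yr, carcass masses 0.25 t (cattle) and 0.09 t (pigs),
#'   `wood_per_worker` 250 m3/yr, `forestry_fraction` 0.10 of agricultural
#'   labour, `g_milk` (slope +0.3) and `g_wood` (slope +0.5).
#' @return A `run_config` list.
#' @export
run_config <- function(variant = c("M", "B"), scenario = c("LE", "SC"),
                       start_year = 1961, end_year = 2011, seed = 1L,
                       demography = list(), technology = list(),
                       land = list(), production = list(), ageing = TRUE) {
  variant <- match.arg(variant)
  scenario <- match.arg(scenario)
  if (!(start_year < end_year)) stopf("start_year must precede end_year")
  dem <- utils::modifyList(list(
    g_labour = response_function(-0.3),
    g_fert_income = response_function(0.1),
    g_mort_income = response_function(-0.2),
    fert_tech_slope = 0.3,
    le_base_rate = 0.04, le_slope = -1.5,
    sc_base_rate = 0.01, sc_slope = 3.0), demography)
  tec <- utils::modifyList(list(a_0 = 0.5), technology)
  lnd <- utils::modifyList(list(
    g_cap = response_function(0.5),
    g_pref = response_function(0.8),
    succession_rate = 1 / 30), land)
  prod <- utils::modifyList(list(
    cattle_fertility = 0.35, cattle_slaughter = 0.33,
    pig_fertility = 0.80, pig_slaughter = 0.78,
    kappa_cattle = 2, kappa_pigs = 2,
    base_milk = 2.7, carcass_cattle = 0.25, carcass_pig = 0.09,
    wood_per_worker = 250, forestry_fraction = 0.10,
    g_milk = response_function(0.3),
    g_wood = response_function(0.5)), production)
  structure(list(variant = variant, scenario = scenario,
                 start_year = start_year, end_year = end_year,
                 seed = as.integer(seed),
                 demography = dem, technology = tec, land = lnd,
                 production = prod, ageing = ageing),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run config: %s-model, scenario %s, %d-%d, seed %d\n",
              x$variant, x$scenario, x$start_year, x$end_year, x$seed))
  invisible(x)
}

# Stable short identifier of a config (metadata only).
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("cfg%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% .Machine$integer.max)
}
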