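# Cohort demography and labour allocation.
#
# The population is carried as three aggregate cohorts: children (< 15),
# adults (15-65) and retirees (> 65).  Ageing uses the uniform-age reading of
# the cohort widths: 1/15 of children and 1/50 of adults move up each year.
# Out-migration removes adults only; the region is open (no return flow).

#' Annual births
#'
#' Gender distribution is assumed equal and the female half of the adult
#' cohort reproduces over a 30-year cycle, so annual newborns are
#' `fertility * (adults / 2) / 30`.
#'
#' @param adults Adult headcount.
#' @param fertility Total fertility rate (births per woman over the cycle).
#' @return Newborns that year (persons, continuous).
#' @export
births <- function(adults, fertility) {
  if (fertility < 0) stopf("fertility must be >= 0")
  stopifnot(adults >= 0)
  fertility * (adults / 2) / 30
}

#' Scenario parameters for out-migration
#'
#' Under scenario `"LE"` (low earnings) the emigration rate responds
#' negatively to regional income: the covariate is the relative income delta
#' and the sensitivity slope must be negative.  Under `"SC"` (structural
#' change) it responds positively to the shift of labour out of agriculture:
#' the covariate is the relative decline of the agricultural labour share and
#' the slope must be positive.
#'
#' @param scenario `"LE"` or `"SC"`.
#' @param base_rate Emigration rate (fraction/yr) at covariate delta 0.
#' @param sensitivity A [response_function()] linking the scenario covariate
#'   delta to the relative change of the rate.
#' @return A `migration_params` list.
#' @export
migration_params <- function(scenario = c("LE", "SC"), base_rate,
                             sensitivity) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(sensitivity, "response_function"),
            base_rate >= 0, base_rate <= 1)
  if (scenario == "LE" && sensitivity$slope > 0)
    stopf("LE sensitivity must be non-positive (emigration falls with income)")
  if (scenario == "SC" && sensitivity$slope < 0)
    stopf("SC sensitivity must be non-negative (emigration rises with sectoral shift)")
  structure(list(scenario = scenario, base_rate = base_rate,
                 sensitivity = sensitivity), class = "migration_params")
}

#' Realized out-migration rate
#'
#' `rate = clip(base_rate * (1 + sensitivity(delta)), 0, 1)`.
#'
#' @param covariate_delta Relative delta of the scenario covariate: income
#'   delta for LE, agricultural-labour-share decline for SC (>= 0 when the
#'   share has fallen).
#' @param params A [migration_params()] object.
#' @return Fraction of adults emigrating that year.
#' @export
migration_rate <- function(covariate_delta, params) {
  stopifnot(inherits(params, "migration_params"))
  if (params$scenario == "SC" && covariate_delta < -1e-12)
    stopf("SC covariate is a share decline and must be >= 0")
  clip(params$base_rate * (1 + predict(params$sensitivity, covariate_delta)),
       0, 1)
}

#' One annual cohort update
#'
#' Flows, all computed on the state at entry: deaths per cohort from the
#' mortality schedule, emigration of adults, ageing transfers (children/15 up,
#' adults/50 up), and births into the child cohort.  The bookkeeping identity
#' `new_total = old_total + births - deaths - emigrants` holds exactly; any
#' cohort pushed below zero is floored with a warning.
#'
#' @param population Named vector `c(children, adults, retirees)`.
#' @param births Newborns that year (see [births()]).
#' @param mortality Named cohort death rates `c(children, adults, retirees)`,
#'   each in \[0, 1\].
#' @param migration_rate Fraction of adults emigrating, in \[0, 1\].
#' @param ageing Apply the 1/15 and 1/50 ageing transfers (default `TRUE`;
#'   turned off only for degenerate equilibrium analyses).
#' @return List with the updated `population` and the realized flows
#'   (`births`, `deaths`, `emigrants`).
#' @export
step_population <- function(population, births, mortality, migration_rate,
                            ageing = TRUE) {
  stopifnot(all(c("children", "adults", "retirees") %in% names(population)),
            all(population >= 0), births >= 0,
            all(mortality >= 0), all(mortality <= 1),
            migration_rate >= 0, migration_rate <= 1)
  ch <- population[["children"]]; ad <- population[["adults"]]
  re <- population[["retirees"]]
  d_ch <- mortality[["children"]] * ch
  d_ad <- mortality[["adults"]] * ad
  d_re <- mortality[["retirees"]] * re
  emig <- migration_rate * ad
  up_ch <- if (ageing) ch / 15 else 0
  up_ad <- if (ageing) ad / 50 else 0
  new <- c(children = ch - d_ch - up_ch + births,
           adults = ad - d_ad - emig - up_ad + up_ch,
           retirees = re - d_re + up_ad)
  new <- floor0(new, "population cohort")
  list(population = new,
       births = births, deaths = d_ch + d_ad + d_re, emigrants = emig)
}

#' Variant fertility pathways
#'
#' The Malthusian pathway uses only the increasing term of the fertility
#' decomposition, raised by income: `malthusian * (1 + g(income_delta))`.
#' The Boserupian pathway inherits both terms; technology deepens only the
#' decreasing (negative) part of the residual, so raising the technology
#' index can lower but never raise Boserupian fertility, and leaves
#' Malthusian fertility untouched.
#'
#' @param malthusian,residual Terms of the [split_fertility()] decomposition
#'   at one year.
#' @param income_delta Lagged relative delta of regional income per adult.
#' @param g_fert_income A [response_function()] with non-negative slope.
#' @param tech_delta Relative delta of the technology index.
#' @param tech_slope Non-negative deepening coefficient.
#' @return Fertility rate (births/woman/yr), floored at 0.
#' @export
m_fertility <- function(malthusian, income_delta, g_fert_income) {
  stopifnot(inherits(g_fert_income, "response_function"))
  max(malthusian * (1 + predict(g_fert_income, income_delta)), 0)
}

#' @rdname m_fertility
#' @export
b_fertility <- function(malthusian, residual, tech_delta, tech_slope) {
  stopifnot(tech_slope >= 0)
  max(malthusian + max(residual, 0) +
        min(residual, 0) * (1 + tech_slope * max(tech_delta, 0)), 0)
}

#' Split the adult labour force between agriculture and industry
#'
#' Technological progress is labour-saving: the agricultural share is the
#' initial share scaled by a negatively sloped response to the technology
#' delta, clipped to \[0, 1\]; industry takes the remainder.
#'
#' @param adults Adult headcount.
#' @param tech_delta Relative delta of the technology covariate.
#' @param initial_share Agricultural labour share in the base year.
#' @param g_labour A [response_function()] with non-positive slope.
#' @return Named vector `c(agricultural, industrial)` summing to `adults`.
#' @export
allocate_labour <- function(adults, tech_delta, initial_share, g_labour) {
  stopifnot(adults >= 0, initial_share >= 0, initial_share <= 1,
            inherits(g_labour, "response_function"))
  if (g_labour$slope > 0)
    stopf("labour response must be labour-saving (non-positive slope)")
  share <- clip(initial_share * (1 + predict(g_labour, tech_delta)), 0, 1)
  c(agricultural = share * adults, industrial = (1 - share) * adults)
}
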