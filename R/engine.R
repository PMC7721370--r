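# Simulation engine.
#
# One run wires the module updates in a fixed annual order:
#   drivers -> technology -> demography -> labour -> land -> livestock ->
#   production/income -> record.
# The variants' causal orderings (M: technology -> land -> population;
# B: population -> technology -> land) are realized through what feeds what:
# the B-model's adoption uses the previous year's population density
# (population precedes technology), and all income responses use the
# previous year's income to avoid simultaneity.

# split_fertility() requires a strictly increasing first step; frozen or
# degenerate driver sets get the trivial decomposition instead.
split_fertility_or_degenerate <- function(actual, years) {
  if (length(actual) >= 2L && actual[2L] > actual[1L])
    split_fertility(actual, years)
  else
    structure(list(years = years, actual = actual, malthusian = actual,
                   residual = rep(0, length(actual))),
              class = "fertility_decomposition")
}

# Fit delta-on-delta response; a flat covariate (frozen drivers) yields the
# zero response rather than a singular-fit error.
fit_response_or_zero <- function(dx, dy) {
  tryCatch(fit_response(dx, dy), error = function(e) response_function(0, 0))
}

#' Run one simulation
#'
#' Executes the annual loop for one (variant, scenario) pair over the
#' configured horizon and returns the recorded trajectory.  All module
#' invariants (exact area conservation, forest monotonicity, population
#' bookkeeping, stocking caps) are re-validated on the assembled trajectory
#' before it is returned.
#'
#' @param config A [run_config()].
#' @param drivers A `driver_set` covering the full horizon (fail-fast
#'   otherwise).
#' @param init A `region_init`.
#' @return An `sd_trajectory`: data frame with one row per year (inclusive of
#'   the start year) and run metadata in attributes.
#' @export
run_simulation <- function(config, drivers, init) {
  stopifnot(inherits(config, "run_config"), inherits(init, "region_init"))
  validate_drivers(drivers)
  years <- config$start_year:config$end_year
  if (!all(years %in% drivers$year))
    stopf("drivers do not cover the horizon %d-%d", config$start_year,
          config$end_year)
  drv <- drivers[match(years, drivers$year), ]
  n <- length(years)
  area_km2 <- init$total_area_ha / 100

  ## ---- setup: base-year anchors and fitted responses ----
  yield_cols <- c(crops = "crop_yield", fodder_crops = "fodder_yield",
                  grassland = "grass_yield")
  yields_0 <- vapply(yield_cols, function(cl) drv[[cl]][1L], numeric(1))
  index <- tech_index(drv$industrial_income, drv$agricultural_income)
  index_delta <- relative_delta(index, index[1L])

  m_deltas <- vapply(yield_cols, function(cl)
    compute_delta_from_series(drv[[cl]], years)$delta, numeric(1))
  g_tech <- lapply(yield_cols, function(cl)
    fit_response_or_zero(index_delta,
                         relative_delta(drv[[cl]], drv[[cl]][1L])))

  fd <- split_fertility_or_degenerate(drv$fertility_actual, years)

  pop <- init$population
  land <- init$land
  cattle <- init$cattle; pigs <- init$pigs
  ag_labour <- init$agricultural_labour
  initial_ag_share <- if (pop[["adults"]] > 0) ag_labour / pop[["adults"]] else 0
  cult_0 <- sum(land[CULTIVATED])
  shares_0 <- land[CULTIVATED] / cult_0
  cap_0 <- if (ag_labour > 0) cult_0 / ag_labour else 1
  density_0 <- max(sum(pop) / area_km2, 1e-9)
  fodder_t0 <- land[["fodder_crops"]] * yields_0[["fodder_crops"]]
  grass_t0 <- land[["grassland"]] * yields_0[["grassland"]]
  ratio_0 <- if (fodder_t0 > 0) grass_t0 / fodder_t0 else 1

  prices_at <- function(i) c(crops = drv$crop_price[i], milk = drv$milk_price[i],
                             beef = drv$beef_price[i], pork = drv$pork_price[i],
                             wood = drv$wood_price[i])
  mort_at <- function(i) c(children = drv$mortality_children[i],
                           adults = drv$mortality_adults[i],
                           retirees = drv$mortality_retirees[i])

  dem <- config$demography
  mig_par <- if (config$scenario == "LE")
    migration_params("LE", dem$le_base_rate, response_function(dem$le_slope))
  else
    migration_params("SC", dem$sc_base_rate, response_function(dem$sc_slope))

  # production/income at a given state (used for year 0 and inside the loop)
  produce <- function(i, yields, land, cattle_in, pigs_in, ag_labour,
                      tech_delta) {
    prod <- config$production
    crop_t <- land[["crops"]] * yields[["crops"]]
    fodder_t <- land[["fodder_crops"]] * yields[["fodder_crops"]]
    grass_t <- land[["grassland"]] * yields[["grassland"]]
    milk <- milk_production(cattle_in, grass_t, fodder_t, ratio_0,
                            prod$base_milk, tech_delta, prod$g_milk)
    beef <- prod$cattle_slaughter * (cattle_in / 2) * prod$carcass_cattle
    pork <- prod$pig_slaughter * pigs_in * prod$carcass_pig
    wood <- wood_production(prod$forestry_fraction * ag_labour,
                            prod$wood_per_worker, tech_delta, prod$g_wood)
    acct <- agricultural_income(
      c(crops = crop_t, milk = milk, beef = beef, pork = pork, wood = wood),
      prices_at(i), ag_labour)
    list(account = acct, crop_t = crop_t, fodder_t = fodder_t,
         grass_t = grass_t, milk = milk, beef = beef, pork = pork,
         wood = wood)
  }

  regional_income_pc <- function(acct, labour, adults, i) {
    if (adults <= 0) return(NA_real_)
    (acct$income + labour[["industrial"]] * drv$industrial_income[i]) / adults
  }

  ## ---- year 0 record ----
  yields <- yields_0
  labour <- c(agricultural = ag_labour,
              industrial = pop[["adults"]] - ag_labour)
  p0 <- produce(1L, yields, land, cattle, pigs, ag_labour, 0)
  income_pc_0 <- regional_income_pc(p0$account, labour, pop[["adults"]], 1L)
  income_pc_lag <- income_pc_0
  ag_share_lag <- initial_ag_share

  rec <- vector("list", n)
  record <- function(i, tech_delta, adoption, fertility, mig, flows, p, land,
                     pop, labour, cattle, pigs, income_pc) {
    rec[[i]] <<- data.frame(
      year = years[i],
      children = pop[["children"]], adults = pop[["adults"]],
      retirees = pop[["retirees"]], population_total = sum(pop),
      labour_agricultural = labour[["agricultural"]],
      labour_industrial = labour[["industrial"]],
      crops_ha = land[["crops"]], fodder_crops_ha = land[["fodder_crops"]],
      grassland_ha = land[["grassland"]],
      intermediate_ha = land[["intermediate"]], forest_ha = land[["forest"]],
      forest_share = 100 * land[["forest"]] / init$total_area_ha,
      cropland_share = 100 * (land[["crops"]] + land[["fodder_crops"]]) /
        init$total_area_ha,
      grassland_share = 100 * land[["grassland"]] / init$total_area_ha,
      cattle = cattle, pigs = pigs,
      yield_crops = yields[["crops"]],
      yield_fodder = yields[["fodder_crops"]],
      yield_grass = yields[["grassland"]],
      tech_index = index[i], tech_delta = tech_delta, adoption = adoption,
      fertility = fertility, migration_rate = mig,
      births = flows[["births"]], deaths = flows[["deaths"]],
      emigrants = flows[["emigrants"]],
      crop_sales_t = p$crop_t, milk_t = p$milk, beef_t = p$beef,
      pork_t = p$pork, wood_m3 = p$wood,
      agricultural_income = p$account$income,
      income_per_ag_worker = p$account$income_per_worker,
      income_per_adult = income_pc)
  }
  record(1L, 0, if (config$variant == "B") config$technology$a_0 else NA_real_,
         drv$fertility_actual[1L], 0,
         c(births = 0, deaths = 0, emigrants = 0), p0, land, pop, labour,
         cattle, pigs, income_pc_0)

  ## ---- annual loop ----
  for (i in 2:n) {
    # technology: exogenous arithmetic increments (M) or adoption of the
    # index-driven response at last year's population density (B)
    if (config$variant == "M") {
      yields <- m_yield_step(yields, m_deltas)
      tech_delta <- mean(relative_delta(yields, yields_0))
      adoption <- NA_real_
    } else {
      density <- sum(pop) / area_km2
      adoption <- adoption_rate(density, config$technology$a_0, density_0)
      yields <- vapply(names(yield_cols), function(k)
        b_yield(yields_0[[k]], g_tech[[k]], index_delta[i], adoption),
        numeric(1))
      names(yields) <- names(yield_cols)
      tech_delta <- index_delta[i]
    }

    # demography: income responses use last year's income
    d_inc <- if (is.na(income_pc_lag) || income_pc_0 <= 0) 0
             else relative_delta(income_pc_lag, income_pc_0)
    fertility <- if (config$variant == "M")
      m_fertility(fd$malthusian[i], d_inc, dem$g_fert_income)
    else
      b_fertility(fd$malthusian[i], fd$residual[i], tech_delta,
                  dem$fert_tech_slope)
    mortality <- mort_at(i)
    if (config$variant == "M")
      mortality <- clip(mortality * (1 + predict(dem$g_mort_income, d_inc)),
                        0, 1)
    mig_cov <- if (config$scenario == "LE") d_inc
               else max((initial_ag_share - ag_share_lag) /
                          max(initial_ag_share, 1e-9), 0)
    mig <- migration_rate(mig_cov, mig_par)
    b <- births(pop[["adults"]], fertility)
    stepped <- step_population(pop, b, mortality, mig, ageing = config$ageing)
    pop <- stepped$population

    # labour
    labour <- allocate_labour(pop[["adults"]], tech_delta, initial_ag_share,
                              dem$g_labour)
    ag_labour <- labour[["agricultural"]]

    # land
    available_ag <- sum(land[CULTIVATED]) + land[["intermediate"]]
    capacity <- farmer_capacity(available_ag, ag_labour, cap_0, tech_delta,
                                config$land$g_cap)
    plan <- allocate_cultivated(ag_labour, capacity, available_ag, tech_delta,
                                shares_0, config$land$g_pref)
    land_new <- step_land(land, plan, config$land$succession_rate)
    audit_land_flows(attr(land_new, "flows"))

    # livestock on the new feed base; slaughter output from entry stocks
    prod <- config$production
    cattle_new <- livestock_step(cattle, land_new[["grassland"]],
                                 prod$cattle_fertility, prod$cattle_slaughter,
                                 prod$kappa_cattle)
    pigs_new <- livestock_step(pigs, land_new[["fodder_crops"]],
                               prod$pig_fertility, prod$pig_slaughter,
                               prod$kappa_pigs)

    p <- produce(i, yields, land_new, cattle, pigs, ag_labour, tech_delta)
    income_pc <- regional_income_pc(p$account, labour, pop[["adults"]], i)

    land <- land_new
    cattle <- cattle_new; pigs <- pigs_new
    record(i, tech_delta, adoption, fertility, mig,
           stepped[c("births", "deaths", "emigrants")], p, land, pop, labour,
           cattle, pigs, income_pc)
    income_pc_lag <- income_pc
    ag_share_lag <- if (pop[["adults"]] > 0) ag_labour / pop[["adults"]]
                    else initial_ag_share
  }

  traj <- do.call(rbind, rec)
  out <- new_sd_trajectory(traj, config = config, init = init,
                           driver_seed = attr(drivers, "seed"))
  validate_trajectory(out)
  out
}

#' Run the four-run comparison matrix
#'
#' Runs {M, B} x {LE, SC} on identical drivers and initialization.
#'
#' @param drivers A `driver_set` shared by the four runs.
#' @param init A shared `region_init`.
#' @param config Template [run_config()]; its variant/scenario fields are
#'   overridden per run.
#' @return An `sd_trajectory_matrix`: named list of four `sd_trajectory`
#'   objects (`M_LE`, `M_SC`, `B_LE`, `B_SC`).
#' @export
run_matrix <- function(drivers, init, config = run_config()) {
  combos <- expand.grid(variant = c("M", "B"), scenario = c("LE", "SC"),
                        stringsAsFactors = FALSE)
  runs <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- config
    cfg$variant <- combos$variant[i]
    cfg$scenario <- combos$scenario[i]
    run_simulation(cfg, drivers, init)
  })
  names(runs) <- paste(combos$variant, combos$scenario, sep = "_")
  structure(runs, class = "sd_trajectory_matrix")
}

#' @export
print.sd_trajectory_matrix <- function(x, ...) {
  cat("simulation matrix:", paste(names(x), collapse = ", "), "\n")
  for (r in x) {
    m <- attr(r, "meta")
    cat(sprintf("  %s-%s: final population %s\n", m$variant, m$scenario,
                format(round(r$population_total[nrow(r)]), big.mark = ",")))
  }
  invisible(x)
}
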