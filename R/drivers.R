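# Synthetic exogenous drivers.
#
# The simulation is driven by national annual series (yields, prices, the two
# sectoral incomes, vital rates) plus a regional emigration rate.  The
# generator emits a seeded synthetic DriverSet with the qualitative structure
# of the Austrian 1961-2011 record: near-linear upward yield trends with
# noise, industrial income growing faster than agricultural income (a rising
# but flattening technology index), a fertility rate peaking in the mid-1960s
# and declining thereafter, declining mortality, and decade-wise constant
# regional emigration rates.

DRIVER_VARS <- c("crop_yield", "fodder_yield", "grass_yield",
                 "crop_price", "milk_price", "beef_price", "pork_price",
                 "wood_price", "industrial_income", "agricultural_income",
                 "fertility_actual", "mortality_children", "mortality_adults",
                 "mortality_retirees", "emigration_rate_regional")

DRIVER_UNITS <- c(
  crop_yield = "t/ha", fodder_yield = "t/ha", grass_yield = "t/ha",
  crop_price = "currency/t", milk_price = "currency/t",
  beef_price = "currency/t", pork_price = "currency/t",
  wood_price = "currency/m3",
  industrial_income = "currency/worker/yr",
  agricultural_income = "currency/worker/yr",
  fertility_actual = "births/woman/yr",
  mortality_children = "1/yr", mortality_adults = "1/yr",
  mortality_retirees = "1/yr",
  emigration_rate_regional = "1/yr")

#' Parameters of the synthetic driver generator
#'
#' Defaults describe the study conditions: a 1961-2011 horizon, Austrian-like
#' yield levels and trends, a technology index (industrial / agricultural
#' income ratio) rising from about 1.3 to about 2.8 and flattening, a total
#' fertility rate of 2.78 in 1961 peaking at 2.82 in 1963 and declining toward
#' 1.4, and a 127,070 ha region of 90,000 inhabitants in which forest and
#' grassland jointly cover 95% of the area in 1961.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param years Simulation horizon (calendar years).
#' @param crop_reference Data frame (`name`, `area_share`, `yield`, `price`)
#'   of representative crop cultures; the base crop yield and price are their
#'   area-weighted means.
#' @param yield_slopes,yield_noise_sd Annual trend (t/ha/yr) and Gaussian
#'   noise s.d. for the three yield series.
#' @param price_trends Multiplicative annual drift of each price series.
#' @param price_noise_sd Relative (lognormal) price noise s.d.
#' @param income_base Industrial income per worker in 1961.
#' @param income_growth Annual geometric growth of industrial income.
#' @param tech_ratio_0,tech_ratio_amp,tech_ratio_tau Saturating shape of the
#'   technology index r(t) = r0 (1 + amp (1 - exp(-t/tau))); agricultural
#'   income is industrial income divided by the index.
#' @param fertility_base,fertility_peak,fertility_peak_year TFR at the start,
#'   at the peak, and the peak calendar year.
#' @param fertility_floor,fertility_decline Asymptote and exponential decline
#'   rate of the post-peak TFR.
#' @param fertility_noise_sd Gaussian noise s.d. on the TFR.
#' @param mortality_base Named cohort mortality rates in 1961
#'   (children, adults, retirees).
#' @param mortality_decline Annual exponential decline rate of mortality.
#' @param emigration_base Mean regional emigration rate (fraction/yr); the
#'   realized rate is constant within each decade.
#' @param emigration_decade_sd Lognormal s.d. of the decade-wise rates.
#' @param total_area_ha Fixed total region area.
#' @param land_shares Named 1961 area shares (crops, fodder_crops, grassland,
#'   intermediate, forest); must sum to 1.
#' @param population_total,population_shares 1961 regional headcount and
#'   cohort shares (children, adults, retirees).
#' @param ag_labour_share Fraction of adults working in agriculture in 1961.
#' @param cattle,pigs 1961 livestock head counts.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(
    seed = 1L,
    years = 1961:2011,
    crop_reference = data.frame(
      name = c("wheat", "barley", "maize", "rye"),
      area_share = c(0.40, 0.25, 0.20, 0.15),
      yield = c(2.8, 2.5, 4.2, 2.2),
      price = c(1400, 1200, 1300, 1100)),
    yield_slopes = c(crop = 0.055, fodder = 0.090, grass = 0.030),
    yield_noise_sd = c(crop = 0.12, fodder = 0.15, grass = 0.08),
    price_trends = c(crop = -0.003, milk = 0.000, beef = 0.001,
                     pork = -0.001, wood = 0.002),
    price_noise_sd = 0.02,
    income_base = 25000,
    income_growth = 0.040,
    tech_ratio_0 = 1.30,
    tech_ratio_amp = 1.25,
    tech_ratio_tau = 20,
    fertility_base = 2.78,
    fertility_peak = 2.82,
    fertility_peak_year = 1963,
    fertility_floor = 1.40,
    fertility_decline = 0.06,
    fertility_noise_sd = 0.012,
    mortality_base = c(children = 0.0030, adults = 0.0045, retirees = 0.0650),
    mortality_decline = 0.008,
    emigration_base = 0.008,
    emigration_decade_sd = 0.25,
    total_area_ha = 127070,
    land_shares = c(crops = 0.02, fodder_crops = 0.02, grassland = 0.40,
                    intermediate = 0.01, forest = 0.55),
    population_total = 90000,
    population_shares = c(children = 0.222, adults = 0.656, retirees = 0.122),
    ag_labour_share = 0.25,
    cattle = 30000,
    pigs = 4000) {
  stopifnot(length(years) >= 2, all(diff(years) == 1))
  if (any(yield_noise_sd < 0) || price_noise_sd < 0 || fertility_noise_sd < 0)
    stopf("noise scales must be >= 0")
  if (!(fertility_peak > fertility_base))
    stopf("fertility must rise from base to peak")
  p <- as.list(environment())
  p$seed <- as.integer(seed)
  class(p) <- "generator_params"
  p
}

# Run fn with a private RNG stream derived from seed, restoring user state.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic driver set
#'
#' @param params A [generator_params()] object.
#' @return A `driver_set`: data frame with one row per year and one column
#'   per driver variable, carrying the seed and units as attributes.  The
#'   output passes the same [validate_drivers()] contract applied to
#'   user-supplied CSVs.
#' @export
generate_drivers <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  yrs <- p$years
  n <- length(yrs)
  t <- yrs - yrs[1L]

  ds <- with_seed(p$seed, function() {
    ref <- weighted_reference(p$crop_reference)
    crop_yield <- ref[["yield"]] + p$yield_slopes[["crop"]] * t +
      stats::rnorm(n, 0, p$yield_noise_sd[["crop"]])
    fodder_yield <- 6.0 + p$yield_slopes[["fodder"]] * t +
      stats::rnorm(n, 0, p$yield_noise_sd[["fodder"]])
    grass_yield <- 4.8 + p$yield_slopes[["grass"]] * t +
      stats::rnorm(n, 0, p$yield_noise_sd[["grass"]])

    price <- function(base, drift) {
      base * (1 + drift)^t *
        exp(stats::rnorm(n, 0, p$price_noise_sd) - p$price_noise_sd^2 / 2)
    }
    crop_price <- price(ref[["price"]], p$price_trends[["crop"]])
    milk_price <- price(2600, p$price_trends[["milk"]])
    beef_price <- price(18000, p$price_trends[["beef"]])
    pork_price <- price(14000, p$price_trends[["pork"]])
    wood_price <- price(350, p$price_trends[["wood"]])

    industrial_income <- p$income_base * (1 + p$income_growth)^t
    ratio <- p$tech_ratio_0 *
      (1 + p$tech_ratio_amp * (1 - exp(-t / p$tech_ratio_tau)))
    agricultural_income <- industrial_income / ratio *
      exp(stats::rnorm(n, 0, 0.01))

    # TFR: linear rise to the peak year, exponential relaxation to the floor.
    fert <- numeric(n)
    pk <- p$fertility_peak_year - yrs[1L]
    rise <- t <= pk
    fert[rise] <- p$fertility_base +
      (p$fertility_peak - p$fertility_base) * t[rise] / max(pk, 1L)
    fert[!rise] <- p$fertility_floor +
      (p$fertility_peak - p$fertility_floor) *
      exp(-p$fertility_decline * (t[!rise] - pk))
    fert <- fert + stats::rnorm(n, 0, p$fertility_noise_sd)
    # the decomposition premise requires a strictly increasing first step
    if (n >= 2L && fert[2L] <= fert[1L]) fert[2L] <- fert[1L] + 0.01

    decline <- exp(-p$mortality_decline * t)
    mortality_children <- p$mortality_base[["children"]] * decline
    mortality_adults <- p$mortality_base[["adults"]] * decline
    mortality_retirees <- p$mortality_base[["retirees"]] * decline

    decade <- (yrs - yrs[1L]) %/% 10L
    dec_rate <- p$emigration_base *
      exp(stats::rnorm(max(decade) + 1L, 0, p$emigration_decade_sd))
    emigration_rate_regional <- dec_rate[decade + 1L]

    data.frame(year = yrs,
               crop_yield = pmax(crop_yield, 0),
               fodder_yield = pmax(fodder_yield, 0),
               grass_yield = pmax(grass_yield, 0),
               crop_price = crop_price, milk_price = milk_price,
               beef_price = beef_price, pork_price = pork_price,
               wood_price = wood_price,
               industrial_income = industrial_income,
               agricultural_income = agricultural_income,
               fertility_actual = pmax(fert, 0),
               mortality_children = mortality_children,
               mortality_adults = mortality_adults,
               mortality_retirees = mortality_retirees,
               emigration_rate_regional = clip(emigration_rate_regional, 0, 1))
  })
  attr(ds, "seed") <- p$seed
  attr(ds, "units") <- DRIVER_UNITS
  class(ds) <- c("driver_set", "data.frame")
  validate_drivers(ds)
  ds
}

#' Validate a driver set
#'
#' One contract shared by the generator and the CSV loader: all variables
#' present, one row per year with no gaps, no missing values, all series
#' non-negative, and a technology index (industrial / agricultural income)
#' that rises over the horizon.
#'
#' @param drivers A `driver_set` or plain data frame in the wide layout.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_drivers <- function(drivers) {
  miss <- setdiff(c("year", DRIVER_VARS), names(drivers))
  if (length(miss)) stopf("driver set missing variables: %s",
                          paste(miss, collapse = ", "))
  if (any(diff(drivers$year) != 1)) stopf("driver years must be consecutive")
  vals <- drivers[DRIVER_VARS]
  if (any(!is.finite(as.matrix(vals)))) stopf("driver set contains missing values")
  if (any(as.matrix(vals) < 0)) stopf("driver series must be non-negative")
  idx <- drivers$industrial_income / drivers$agricultural_income
  if (mean(diff(idx)) <= 0)
    stopf("technology index must rise on average over the horizon")
  invisible(drivers)
}

#' @export
print.driver_set <- function(x, ...) {
  cat(sprintf("synthetic driver set: %d years (%d-%d), seed %s\n",
              nrow(x), min(x$year), max(x$year),
              format(attr(x, "seed"))))
  cat(sprintf("  technology index %.2f -> %.2f\n",
              x$industrial_income[1L] / x$agricultural_income[1L],
              x$industrial_income[nrow(x)] / x$agricultural_income[nrow(x)]))
  invisible(x)
}

#' Generate the 1961 regional initialization
#'
#' @param params A [generator_params()] object.
#' @return A `region_init` list: `population` (children, adults, retirees),
#'   `land` (crops, fodder_crops, grassland, intermediate, forest, in ha,
#'   summing to the configured total), `cattle`, `pigs`,
#'   `agricultural_labour`, `total_area_ha`.
#' @export
generate_region_init <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  if (abs(sum(p$land_shares) - 1) > 1e-9)
    stopf("land shares must sum to 1")
  if (abs(sum(p$population_shares) - 1) > 1e-9)
    stopf("population shares must sum to 1")
  land <- p$land_shares * p$total_area_ha
  pop <- round(p$population_shares * p$population_total)
  pop[["adults"]] <- p$population_total - pop[["children"]] - pop[["retirees"]]
  init <- list(
    population = c(children = pop[["children"]], adults = pop[["adults"]],
                   retirees = pop[["retirees"]]),
    land = c(crops = land[["crops"]], fodder_crops = land[["fodder_crops"]],
             grassland = land[["grassland"]],
             intermediate = land[["intermediate"]],
             forest = land[["forest"]]),
    cattle = p$cattle, pigs = p$pigs,
    agricultural_labour = round(p$ag_labour_share * pop[["adults"]]),
    total_area_ha = p$total_area_ha)
  if (init$agricultural_labour > init$population[["adults"]])
    stopf("agricultural labour cannot exceed adults")
  class(init) <- "region_init"
  init
}

#' @export
print.region_init <- function(x, ...) {
  cat(sprintf("region init: %s inhabitants, %s ha (%.0f%% forest+grassland)\n",
              format(sum(x$population), big.mark = ","),
              format(x$total_area_ha, big.mark = ","),
              100 * (x$land[["forest"]] + x$land[["grassland"]]) / x$total_area_ha))
  invisible(x)
}

#' Generate a pseudo-empirical regional series
#'
#' The study's regional observation record (population census, land-cover
#' statistics) is not distributable; this emits a synthetic stand-in with its
#' qualitative features -- population rising a few percent to 1980 and then
#' oscillating around 90,000, children declining and retirees rising, forest
#' share creeping up, grassland share declining -- for exercising the
#' evaluation stage.  It is labelled pseudo-empirical throughout.
#'
#' @param params A [generator_params()] object.
#' @return Data frame with columns `year`, `population_total`, `children`,
#'   `adults`, `retirees`, `forest_share`, `cropland_share`,
#'   `grassland_share` (shares as % of total area).
#' @export
generate_empirical <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  yrs <- p$years
  t <- yrs - yrs[1L]
  n <- length(yrs)
  with_seed(p$seed + 104729L, function() {
    base <- p$population_total * 0.97
    growth <- pmin(t / 19, 1) * 0.03        # +3% by 1980, then stagnation
    osc <- 0.006 * sin(2 * pi * t / 17) + stats::rnorm(n, 0, 0.003)
    pop <- base * (1 + growth) * (1 + osc * (t > 19))
    ch_share <- seq(p$population_shares[["children"]], 0.14, length.out = n)
    re_share <- seq(p$population_shares[["retirees"]], 0.19, length.out = n)
    sat <- 1 - exp(-t / 18)
    forest <- 100 * (p$land_shares[["forest"]] + 0.035 * sat)
    cropland <- 100 * (p$land_shares[["crops"]] + p$land_shares[["fodder_crops"]]
                       + 0.030 * sat)
    grassland <- 100 * (p$land_shares[["grassland"]] - 0.055 * sat)
    data.frame(year = yrs,
               population_total = pop,
               children = pop * ch_share,
               adults = pop * (1 - ch_share - re_share),
               retirees = pop * re_share,
               forest_share = forest,
               cropland_share = cropland,
               grassland_share = grassland)
  })
}

#' Write / read a driver set as tidy CSV
#'
#' The on-disk format is long: columns `year`, `variable`, `value`, `unit`.
#' The reader completes interior gaps by linear interpolation and extends edge
#' gaps with the nearest observed value, so a price series that starts after
#' the simulation start (e.g. constant prices assumed for 1961-66) is
#' back-filled with its first observation; the completed set is validated with
#' [validate_drivers()].
#'
#' @param drivers A `driver_set`.
#' @param path File path.
#' @return `write_drivers()` the path invisibly; `read_drivers()` a
#'   `driver_set`.
#' @export
write_drivers <- function(drivers, path) {
  long <- do.call(rbind, lapply(DRIVER_VARS, function(v) {
    data.frame(year = drivers$year, variable = v, value = drivers[[v]],
               unit = DRIVER_UNITS[[v]])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drivers
#' @param years Horizon the completed series must cover (default: the range
#'   of years present in the file).
#' @export
read_drivers <- function(path, years = NULL) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("year", "variable", "value") %in% names(long)))
  if (is.null(years)) years <- seq(min(long$year), max(long$year))
  wide <- data.frame(year = years)
  for (v in DRIVER_VARS) {
    sub <- long[long$variable == v, ]
    if (nrow(sub) == 0L) stopf("driver CSV missing variable %s", v)
    wide[[v]] <- interpolate_gaps(sub$year, sub$value, full_years = years)$value
  }
  attr(wide, "units") <- DRIVER_UNITS
  class(wide) <- c("driver_set", "data.frame")
  validate_drivers(wide)
  wide
}

#' Write / read a regional initialization as CSV
#'
#' Flat two-column CSV (`field`, `value`).
#' @param init A `region_init`.
#' @param path File path.
#' @export
write_region_init <- function(init, path) {
  kv <- c(as.list(init$population), as.list(init$land),
          list(cattle = init$cattle, pigs = init$pigs,
               agricultural_labour = init$agricultural_labour,
               total_area_ha = init$total_area_ha))
  utils::write.csv(data.frame(field = names(kv), value = unlist(kv)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_init
#' @export
read_region_init <- function(path) {
  kv <- utils::read.csv(path, stringsAsFactors = FALSE)
  val <- stats::setNames(kv$value, kv$field)
  init <- list(
    population = c(children = val[["children"]], adults = val[["adults"]],
                   retirees = val[["retirees"]]),
    land = c(crops = val[["crops"]], fodder_crops = val[["fodder_crops"]],
             grassland = val[["grassland"]],
             intermediate = val[["intermediate"]], forest = val[["forest"]]),
    cattle = val[["cattle"]], pigs = val[["pigs"]],
    agricultural_labour = val[["agricultural_labour"]],
    total_area_ha = val[["total_area_ha"]])
  class(init) <- "region_init"
  init
}
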