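# Shared fixtures, built in code.  The default-seed driver set, init and
# four-run matrix are computed once per test session and reused.

fixture_env <- new.env(parent = emptyenv())

fix_params <- function(seed = 42L) generator_params(seed = seed)

fix_drivers <- function() {
  if (is.null(fixture_env$drivers))
    fixture_env$drivers <- generate_drivers(fix_params())
  fixture_env$drivers
}

fix_init <- function() {
  if (is.null(fixture_env$init))
    fixture_env$init <- generate_region_init(fix_params())
  fixture_env$init
}

fix_matrix <- function() {
  if (is.null(fixture_env$matrix))
    fixture_env$matrix <- run_matrix(fix_drivers(), fix_init(),
                                     run_config(seed = 42L))
  fixture_env$matrix
}

# A frozen driver set: every series constant at its base-year value except
# vital rates, which are zeroed.  Used for equilibrium fixed-point checks.
frozen_drivers <- function(template = fix_drivers()) {
  d <- template
  for (v in setdiff(names(d), "year")) d[[v]] <- d[[v]][1L]
  d$mortality_children <- d$mortality_adults <- d$mortality_retirees <- 0
  d$fertility_actual <- 0
  d$emigration_rate_regional <- 0
  # keep the index-rising validation satisfied by an infinitesimal drift
  d$industrial_income <- d$industrial_income * (1 + 1e-12 * seq_len(nrow(d)))
  d
}

# Init with an empty intermediate pool (no succession flux at equilibrium).
equilibrium_init <- function() {
  generate_region_init(generator_params(
    seed = 42L,
    land_shares = c(crops = 0.02, fodder_crops = 0.02, grassland = 0.41,
                    intermediate = 0, forest = 0.55)))
}

# Config with every change pathway switched off.
equilibrium_config <- function(variant = "M") {
  run_config(variant = variant, scenario = "LE", ageing = FALSE,
             demography = list(le_base_rate = 0,
                               g_fert_income = response_function(0),
                               g_mort_income = response_function(0)),
             production = list(cattle_fertility = 0.3, cattle_slaughter = 0.3,
                               pig_fertility = 0.3, pig_slaughter = 0.3))
}
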