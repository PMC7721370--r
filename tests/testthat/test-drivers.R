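test_that("the generator is deterministic under seed and seeds differ", {
  a <- generate_drivers(generator_params(seed = 5))
  b <- generate_drivers(generator_params(seed = 5))
  c <- generate_drivers(generator_params(seed = 6))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$crop_yield, c$crop_yield))
})

test_that("zero noise gives exactly affine yield trends", {
  p <- generator_params(seed = 1,
                        yield_noise_sd = c(crop = 0, fodder = 0, grass = 0))
  d <- generate_drivers(p)
  expect_equal(max(abs(diff(d$crop_yield, differences = 2))), 0,
               tolerance = 1e-10)
  expect_equal(diff(d$crop_yield)[1], p$yield_slopes[["crop"]],
               tolerance = 1e-10)
})

test_that("default fertility peaks by 1970 and ends below its 1961 level", {
  d <- fix_drivers()
  expect_lte(d$year[which.max(d$fertility_actual)], 1970)
  expect_lt(d$fertility_actual[d$year == 2011],
            d$fertility_actual[d$year == 1961])
})

test_that("industrial income outgrows agricultural income", {
  d <- fix_drivers()
  idx <- d$industrial_income / d$agricultural_income
  expect_gt(idx[length(idx)], idx[1])
  expect_gt(mean(diff(idx)), 0)
})

test_that("generated sets pass the same validation contract as loaded CSVs", {
  d <- fix_drivers()
  expect_silent(validate_drivers(d))
  path <- withr::local_tempfile(fileext = ".csv")
  write_drivers(d, path)
  d2 <- read_drivers(path)
  expect_silent(validate_drivers(d2))
  expect_equal(d2$crop_yield, d$crop_yield, tolerance = 1e-9)
  expect_equal(d2$mortality_retirees, d$mortality_retirees, tolerance = 1e-9)
})

test_that("price series starting after 1961 are back-filled on load", {
  d <- fix_drivers()
  path <- withr::local_tempfile(fileext = ".csv")
  write_drivers(d, path)
  long <- read.csv(path)
  # drop crop prices before 1966, as in a series observed only from 1966 on
  long <- long[!(long$variable == "crop_price" & long$year < 1966), ]
  write.csv(long, path, row.names = FALSE)
  d2 <- read_drivers(path, years = 1961:2011)
  first_obs <- d$crop_price[d$year == 1966]
  expect_true(all(d2$crop_price[d2$year < 1966] ==
                    d2$crop_price[d2$year == 1966]))
  expect_equal(d2$crop_price[d2$year == 1966], first_obs, tolerance = 1e-9)
})

test_that("interior driver gaps are interpolated linearly on load", {
  d <- fix_drivers()
  path <- withr::local_tempfile(fileext = ".csv")
  write_drivers(d, path)
  long <- read.csv(path)
  long <- long[!(long$variable == "industrial_income" &
                   long$year %in% 1975:1979), ]
  write.csv(long, path, row.names = FALSE)
  d2 <- read_drivers(path)
  lo <- d$industrial_income[d$year == 1974]
  hi <- d$industrial_income[d$year == 1980]
  expect_equal(d2$industrial_income[d2$year == 1977], (lo + hi) / 2,
               tolerance = 1e-9)
})

test_that("the default region fixture matches the 1961 land structure", {
  init <- fix_init()
  expect_equal(sum(init$land), 127070)
  expect_equal((init$land[["forest"]] + init$land[["grassland"]]) /
                 init$total_area_ha, 0.95)
  expect_true(all(init$land >= 0))
  expect_gte(init$population[["adults"]], init$agricultural_labour)
})

test_that("degenerate all-adults population fixtures are accepted", {
  init <- generate_region_init(generator_params(
    population_shares = c(children = 0, adults = 1, retirees = 0)))
  expect_equal(init$population[["children"]], 0)
  expect_equal(init$population[["retirees"]], 0)
  expect_equal(sum(init$population), 90000)
})

test_that("misconfigured shares are rejected", {
  expect_error(generate_region_init(generator_params(
    land_shares = c(crops = 0.1, fodder_crops = 0.1, grassland = 0.4,
                    intermediate = 0.1, forest = 0.5))), "sum to 1")
  expect_error(generator_params(yield_noise_sd = c(crop = -1, fodder = 0,
                                                   grass = 0)), "noise")
})

test_that("region init round-trips through CSV", {
  init <- fix_init()
  path <- withr::local_tempfile(fileext = ".csv")
  write_region_init(init, path)
  back <- read_region_init(path)
  expect_equal(back$land, init$land)
  expect_equal(back$population, init$population)
  expect_equal(back$total_area_ha, init$total_area_ha)
})

test_that("the pseudo-empirical series has the observed regional features", {
  emp <- generate_empirical(fix_params())
  n <- nrow(emp)
  # a few percent growth to 1980, then oscillation around 90,000
  expect_gt(emp$population_total[emp$year == 1980],
            emp$population_total[1])
  expect_lt(abs(emp$population_total[n] - 90000) / 90000, 0.05)
  expect_lt(emp$children[n] / emp$population_total[n],
            emp$children[1] / emp$population_total[1])
  expect_gt(emp$forest_share[n], emp$forest_share[1])
  expect_lt(emp$grassland_share[n], emp$grassland_share[1])
})
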