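test_that("births follow the 30-year reproductive convention", {
  expect_equal(births(6000, 2.0), 200)
  expect_equal(births(0, 2.0), 0)
  expect_equal(births(6000, 0), 0)
  expect_error(births(6000, -0.1), "fertility")
})

test_that("migration rates respect the scenario sign contracts", {
  le <- migration_params("LE", 0.05, response_function(-2))
  expect_equal(migration_rate(0, le), 0.05)
  expect_lt(migration_rate(0.3, le), 0.05)   # income up -> emigration down
  expect_equal(migration_rate(5, le), 0)     # clipped at 0

  sc <- migration_params("SC", 0.02, response_function(3))
  expect_equal(migration_rate(0, sc), 0.02)
  expect_gt(migration_rate(0.4, sc), 0.02)   # sectoral shift -> emigration up
  expect_error(migration_rate(-0.2, sc), "share decline")

  # wrong sensitivity sign for the scenario is a contract error
  expect_error(migration_params("LE", 0.05, response_function(2)),
               "non-positive")
  expect_error(migration_params("SC", 0.05, response_function(-2)),
               "non-negative")
})

test_that("the cohort step has identity and boundary behaviour", {
  pop <- c(children = 1000, adults = 5000, retirees = 800)
  zero_m <- c(children = 0, adults = 0, retirees = 0)
  still <- step_population(pop, 0, zero_m, 0, ageing = FALSE)
  expect_equal(still$population, pop)

  gone <- step_population(pop, 0, zero_m, 1, ageing = FALSE)
  expect_equal(gone$population[["adults"]], 0)
  expect_equal(gone$population[["children"]], 1000)
  expect_equal(gone$population[["retirees"]], 800)
  expect_equal(gone$emigrants, 5000)
})

test_that("population bookkeeping identity holds exactly for random steps", {
  set.seed(3)
  for (rep in 1:40) {
    pop <- c(children = runif(1, 0, 5e4), adults = runif(1, 0, 1e5),
             retirees = runif(1, 0, 3e4))
    m <- c(children = runif(1, 0, 0.05), adults = runif(1, 0, 0.05),
           retirees = runif(1, 0, 0.2))
    b <- runif(1, 0, 3000)
    mig <- runif(1, 0, 0.3)
    out <- step_population(pop, b, m, mig)
    expect_equal(sum(out$population) - sum(pop),
                 out$births - out$deaths - out$emigrants, tolerance = 1e-9)
  }
})

test_that("30-year constant-rate projection matches a matrix-projection oracle", {
  f <- 2.2
  m <- c(children = 0.004, adults = 0.005, retirees = 0.06)
  mig <- 0.015
  # independent Leslie-style projection matrix over (children, adults, retirees)
  A <- matrix(c(1 - m[["children"]] - 1 / 15, f / 60,                        0,
                1 / 15, 1 - m[["adults"]] - mig - 1 / 50,                    0,
                0,      1 / 50,                     1 - m[["retirees"]]),
              nrow = 3, byrow = TRUE)
  n <- c(20000, 59000, 11000)
  for (i in 1:30) n <- A %*% n

  pop <- c(children = 20000, adults = 59000, retirees = 11000)
  for (i in 1:30) {
    b <- births(pop[["adults"]], f)
    pop <- step_population(pop, b, m, mig)$population
  }
  expect_equal(unname(pop), as.vector(n), tolerance = 1e-9)
})

test_that("labour allocation is anchored and labour-saving", {
  g <- response_function(-0.5)
  out <- allocate_labour(1000, 0, 0.4, g)
  expect_equal(out[["agricultural"]], 400)
  expect_equal(sum(out), 1000)

  # adults 1000, initial share 0.4, response value -0.25 -> 0.4 * 0.75 * 1000
  g25 <- response_function(-0.25)
  expect_equal(allocate_labour(1000, 1, 0.4, g25)[["agricultural"]], 300)

  shares <- vapply(seq(0, 2, 0.25),
                   function(d) allocate_labour(1000, d, 0.4, g)[["agricultural"]],
                   numeric(1))
  expect_true(all(diff(shares) <= 0))
  expect_true(all(shares >= 0))
  expect_error(allocate_labour(1000, 0, 0.4, response_function(1)),
               "labour-saving")
})

test_that("fertility pathways respond to technology as the theories posit", {
  g_inc <- response_function(0.1)
  # Malthusian: income raises fertility, technology is absent
  expect_gt(m_fertility(2.5, 0.5, g_inc), m_fertility(2.5, 0, g_inc))
  expect_equal(m_fertility(2.5, 0, g_inc), 2.5)
  # Boserupian: raising the index never raises fertility
  for (res in c(-0.8, -0.1, 0, 0.2)) {
    f <- vapply(seq(0, 2, 0.2), function(d) b_fertility(3, res, d, 0.4),
                numeric(1))
    expect_true(all(diff(f) <= 1e-12))
  }
  # at zero tech delta both terms reconstruct the actual rate
  expect_equal(b_fertility(3, -0.7, 0, 0.4), 2.3)
  expect_gte(b_fertility(3, -5, 2, 0.4), 0)
})
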