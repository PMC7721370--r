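make_plan <- function(targets) {
  structure(list(targets = targets, total = sum(targets)),
            class = "cultivation_plan")
}

test_that("farmer capacity is the binding minimum of land and technology", {
  g <- response_function(1, 0)
  expect_equal(farmer_capacity(1e6, 100, 10, 0, g), 10)
  expect_equal(farmer_capacity(500, 100, 10, 0, g), 5)  # land-limited branch
  expect_equal(farmer_capacity(1e6, 100, 10, 0.5, g), 15)
  expect_equal(farmer_capacity(1e6, 0, 10, 0, g), 0)
})

test_that("cultivation allocation is anchored and shifts toward crops", {
  shares <- c(crops = 0.1, fodder_crops = 0.1, grassland = 0.8)
  g <- response_function(0.8)
  plan0 <- allocate_cultivated(100, 12, 1e6, 0, shares, g)
  expect_equal(plan0$total, 1200)
  expect_equal(unname(plan0$targets / plan0$total), unname(shares))

  deltas <- seq(0, 2, 0.25)
  plans <- lapply(deltas, function(d)
    allocate_cultivated(100, 12, 1e6, d, shares, g))
  crop_share <- vapply(plans, function(p) p$targets[["crops"]] / p$total,
                       numeric(1))
  grass_share <- vapply(plans, function(p) p$targets[["grassland"]] / p$total,
                        numeric(1))
  expect_true(all(diff(crop_share) >= 0))
  expect_true(all(diff(grass_share) <= 0))
  expect_true(all(vapply(plans, function(p)
    abs(sum(p$targets) - p$total) < 1e-9, logical(1))))

  # capped by available agricultural land
  expect_equal(allocate_cultivated(100, 12, 900, 0, shares, g)$total, 900)
})

test_that("succession converts 1/30 of the intermediate stock to forest", {
  state <- c(crops = 2000, fodder_crops = 1000, grassland = 40000,
             intermediate = 3000, forest = 60000)
  plan <- make_plan(state[c("crops", "fodder_crops", "grassland")])
  out <- step_land(state, plan)
  expect_equal(out[["forest"]] - state[["forest"]], 100)
  expect_equal(out[["intermediate"]], 2900)
  expect_equal(sum(out), sum(state))
})

test_that("a plan equal to the current state with no intermediate is a fixed point", {
  state <- c(crops = 2000, fodder_crops = 1000, grassland = 40000,
             intermediate = 0, forest = 60000)
  plan <- make_plan(state[c("crops", "fodder_crops", "grassland")])
  out <- step_land(state, plan)
  expect_equal(as.numeric(out), as.numeric(state))
})

test_that("with no recultivation the intermediate pool decays geometrically", {
  I0 <- 5000
  state <- c(crops = 1000, fodder_crops = 500, grassland = 20000,
             intermediate = I0, forest = 100570)
  plan <- make_plan(state[c("crops", "fodder_crops", "grassland")])
  for (t in 1:30) state <- step_land(state, plan)
  expect_equal(state[["intermediate"]], I0 * (29 / 30)^30, tolerance = 1e-12)
  expect_equal(state[["forest"]], 100570 + I0 * (1 - (29 / 30)^30),
               tolerance = 1e-12)
})

test_that("area is conserved and forest monotone under random plans", {
  set.seed(21)
  state <- c(crops = 2541, fodder_crops = 2541, grassland = 50828,
             intermediate = 1271, forest = 69889)
  total <- sum(state)
  for (t in 1:60) {
    avail <- sum(state[c("crops", "fodder_crops", "grassland", "intermediate")])
    tgt <- runif(3)
    tgt <- tgt / sum(tgt) * runif(1, 0.5, 1) * avail
    names(tgt) <- c("crops", "fodder_crops", "grassland")
    old_forest <- state[["forest"]]
    state <- step_land(state, make_plan(tgt))
    expect_lt(abs(sum(state) - total), 1e-6)
    expect_gte(state[["forest"]], old_forest)
    expect_true(all(state >= 0))
  }
})

test_that("over-demanding plans are truncated with a warning", {
  state <- c(crops = 1000, fodder_crops = 500, grassland = 2000,
             intermediate = 500, forest = 123070)
  plan <- make_plan(c(crops = 3000, fodder_crops = 2000, grassland = 4000))
  expect_warning(out <- step_land(state, plan), "truncated")
  expect_equal(sum(out), sum(state))
  expect_equal(out[["intermediate"]], 0)
})

test_that("no structural pathway leads out of forest", {
  state <- c(crops = 2000, fodder_crops = 1000, grassland = 40000,
             intermediate = 3000, forest = 60000)
  plan <- make_plan(c(crops = 2500, fodder_crops = 800, grassland = 39000))
  out <- step_land(state, plan)
  flows <- attr(out, "flows")
  expect_true(audit_land_flows(flows))
  expect_true(all(flows["forest", colnames(flows) != "forest"] == 0))
  # and the succession flow is the only inflow to forest
  expect_equal(sum(flows[, "forest"] > 0), 1L)
})
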