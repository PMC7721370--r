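test_that("relative deltas are signed deviations from the base value", {
  expect_equal(relative_delta(110, 100), 0.10)
  expect_equal(relative_delta(100, 100), 0)
  expect_equal(relative_delta(50, 100), -0.50)
  expect_equal(relative_delta(c(120, 80), 100), c(0.2, -0.2))
  expect_error(relative_delta(1, 0), "baseline")
  expect_error(relative_delta(1, -2), "baseline")
})

test_that("response fits reproduce exact lines and reject degenerate input", {
  x <- c(-0.2, 0, 0.1, 0.4)
  g <- fit_response(x, 2 * x)
  expect_equal(g$slope, 2)
  expect_equal(g$intercept, 0)
  expect_equal(g$fit_r2, 1)
  expect_equal(g$fit_n, 4L)

  g0 <- fit_response(x, rep(0, 4))
  expect_equal(g0$slope, 0)
  expect_equal(g0$intercept, 0)

  expect_error(fit_response(rep(0.3, 5), 1:5 / 10), "singular")
  expect_error(fit_response(1:3 / 10, 1:2 / 10), "equal-length")
})

test_that("noisy response fit matches the closed-form OLS oracle", {
  set.seed(7)
  for (rep in 1:5) {
    x <- runif(50, -0.5, 0.5)
    y <- 0.5 * x + rnorm(50, 0, 0.05)
    g <- fit_response(x, y)
    # independent closed-form OLS from sums
    sxx <- sum((x - mean(x))^2)
    slope_hat <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept_hat <- mean(y) - slope_hat * mean(x)
    expect_equal(g$slope, slope_hat, tolerance = 1e-12)
    expect_equal(g$intercept, intercept_hat, tolerance = 1e-12)
    # slope recovered within 3 standard errors of the truth
    sigma2 <- sum((y - intercept_hat - slope_hat * x)^2) / 48
    se <- sqrt(sigma2 / sxx)
    expect_lt(abs(g$slope - 0.5), 3 * se)
  }
})

test_that("two-point fits equal the closed-form line through the points", {
  g <- fit_response(c(0.1, 0.3), c(0.05, 0.45))
  slope <- (0.45 - 0.05) / (0.3 - 0.1)
  expect_equal(g$slope, slope)
  expect_equal(g$intercept, 0.05 - slope * 0.1)
  expect_equal(g$fit_n, 2L)
})

test_that("applying a response scales the base value by 1 + g(delta)", {
  expect_equal(apply_response(100, response_function(0, 0), 0.7), 100)
  expect_equal(apply_response(100, response_function(1, 0), 0.2), 120)
  expect_equal(apply_response(100, response_function(1, 0), -0.3), 70)
  # evaluating at delta = 0 returns the intercept effect for any slope
  g <- response_function(5, 0.25)
  expect_equal(apply_response(80, g, relative_delta(80, 80)), 80 * 1.25)
  expect_warning(out <- apply_response(100, response_function(1, 0), -1.5),
                 "floored")
  expect_equal(out, 0)
  expect_error(apply_response(-1, g, 0), "baseline")
})

test_that("fertility split extends the first two observations and reconstructs", {
  fd <- split_fertility(c(2.0, 2.1, 2.2, 2.3))
  expect_equal(fd$residual, rep(0, 4))
  expect_equal(fd$malthusian, c(2.0, 2.1, 2.2, 2.3))

  fd2 <- split_fertility(c(2.0, 2.1, 1.9))
  expect_equal(fd2$malthusian, c(2.0, 2.1, 2.2))
  expect_equal(fd2$residual, c(0, 0, -0.3))

  expect_error(split_fertility(c(2.1, 2.0, 1.9)), "strictly increasing")
  expect_error(split_fertility(2.5), "length")
})

test_that("fertility reconstruction identity is exact for random series", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(3:60, 1)
    actual <- cumsum(c(runif(1, 1, 3), runif(1, 0.01, 0.1),
                       rnorm(n - 2, 0, 0.2)))
    fd <- split_fertility(actual)
    # identity at double precision: residual is defined as the difference
    expect_lt(max(abs(fd$malthusian + fd$residual - fd$actual)), 1e-12)
    # malthusian term is affine with non-negative slope
    expect_true(all(diff(fd$malthusian, differences = 2) < 1e-12))
    expect_gte(fd$malthusian[2] - fd$malthusian[1], 0)
  }
})

test_that("reference products are share-weighted and permutation invariant", {
  one <- data.frame(name = "a", area_share = 1, yield = 4.2, price = 130)
  expect_equal(weighted_reference(one), c(yield = 4.2, price = 130))

  two <- data.frame(name = c("a", "b"), area_share = c(0.5, 0.5),
                    yield = c(4, 6), price = c(100, 200))
  expect_equal(weighted_reference(two)[["yield"]], 5)

  four <- data.frame(name = letters[1:4],
                     area_share = c(0.4, 0.3, 0.2, 0.1),
                     yield = c(3.1, 5.2, 2.4, 7.7),
                     price = c(110, 90, 150, 60))
  # independent dot-product oracle
  expect_equal(weighted_reference(four)[["yield"]],
               0.4 * 3.1 + 0.3 * 5.2 + 0.2 * 2.4 + 0.1 * 7.7)
  expect_equal(weighted_reference(four)[["price"]],
               0.4 * 110 + 0.3 * 90 + 0.2 * 150 + 0.1 * 60)
  perm <- four[c(3, 1, 4, 2), ]
  expect_equal(weighted_reference(perm), weighted_reference(four))

  bad <- four; bad$area_share <- bad$area_share * 1.1
  expect_error(weighted_reference(bad), "share normalization")
})

test_that("gap interpolation is linear inside and constant at the edges", {
  out <- interpolate_gaps(c(1960, 1970), c(10, 20))
  expect_equal(out$value[out$year == 1965], 15)

  full <- interpolate_gaps(1960:1965, c(1, 2, 3, 4, 5, 6))
  expect_equal(full$value, 1:6)

  const <- interpolate_gaps(c(1974, 2011), c(8, 8))
  expect_true(all(const$value == 8))
  expect_equal(nrow(const), 2011 - 1974 + 1)

  # edge extension: values requested before the first observation
  edge <- interpolate_gaps(c(1966, 1970), c(5, 9), full_years = 1961:1970)
  expect_true(all(edge$value[edge$year < 1966] == 5))

  expect_error(interpolate_gaps(numeric(0), numeric(0)), "empty")
})
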