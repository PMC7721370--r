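# Generic functional-relationship machinery.
#
# Every behavioural linkage in the models is expressed the same way: a driver
# is reduced to its relative deviation from the 1961 base year,
# delta = (x_t - x_0) / x_0, a linear response g is fitted (or configured) on
# such deltas, and the response is applied multiplicatively,
# y_t = x_0 * (1 + g(delta)).  Because deltas are signed, the same device
# models forward (g > 0) and backward (g < 0) development.

#' Relative deviation from a base value
#'
#' Computes `(x_t - x_0) / x_0`, the dimensionless deviation of a driver from
#' its base-year value.  This is the sole covariate form used by all response
#' functions in the package.
#'
#' @param x_t Observed value(s) at time t.
#' @param x_0 Base-year value; must be strictly positive.
#' @return Numeric vector of dimensionless deltas; 0 when `x_t == x_0`,
#'   bounded below by -1 when `x_t >= 0`.
#' @examples
#' relative_delta(110, 100)  # 0.10
#' relative_delta(50, 100)   # -0.50, backward development
#' @export
relative_delta <- function(x_t, x_0) {
  if (any(!is.finite(x_0)) || any(x_0 <= 0))
    stopf("invalid baseline: x_0 must be finite and > 0")
  (x_t - x_0) / x_0
}

#' Fit a linear response function on relative deltas
#'
#' Ordinary-least-squares line through pairs of relative deltas.  The fitted
#' object is the `g` in `y_t = x_0 * (1 + g(delta))` and can be evaluated with
#' [predict()][predict.response_function].
#'
#' @param deltas_x Covariate deltas (length >= 2, at least two distinct).
#' @param deltas_y Response deltas, same length.
#' @return A `response_function` object with fields `slope`, `intercept`,
#'   `fit_n` and `fit_r2`.
#' @seealso [response_function()] for a directly parameterised response.
#' @export
fit_response <- function(deltas_x, deltas_y) {
  deltas_x <- as.numeric(deltas_x)
  deltas_y <- as.numeric(deltas_y)
  n <- length(deltas_x)
  if (n < 2L || length(deltas_y) != n)
    stopf("need two equal-length delta series of length >= 2")
  if (length(unique(deltas_x)) < 2L)
    stopf("singular fit: all covariate deltas are equal")
  fit <- stats::lm(deltas_y ~ deltas_x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((deltas_y - mean(deltas_y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1  # constant fitted exactly
  response_function(slope = unname(stats::coef(fit)[2L]),
                    intercept = unname(stats::coef(fit)[1L]),
                    fit_n = n, fit_r2 = r2)
}

#' Construct a response function directly
#'
#' @param slope,intercept Line coefficients on the delta scale.
#' @param fit_n Number of points behind the fit (2 for a configured line).
#' @param fit_r2 Coefficient of determination of the fit.
#' @return A `response_function` object.
#' @export
response_function <- function(slope, intercept = 0, fit_n = 2L, fit_r2 = NA_real_) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept,
                 fit_n = as.integer(fit_n), fit_r2 = fit_r2),
            class = "response_function")
}

#' @rdname response_function
#' @param object,x A `response_function`.
#' @param newdata Deltas at which to evaluate the line.
#' @param ... Unused.
#' @export
predict.response_function <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' @rdname response_function
#' @export
coef.response_function <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @rdname response_function
#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("response function g(d) = %.4g %+.4g * d  (n = %d, r2 = %s)\n",
              x$intercept, x$slope, x$fit_n,
              if (is.na(x$fit_r2)) "NA" else sprintf("%.3f", x$fit_r2)))
  invisible(x)
}

#' Apply a response function to a base value
#'
#' Implements `y_t = x_0 * (1 + g(delta))`.  Results below zero (possible
#' under strong backward development) are floored at 0 with a warning.
#'
#' @param x_0 Positive base-year value.
#' @param g A `response_function`.
#' @param delta Relative delta of the covariate.
#' @return `x_0 * (1 + g(delta))`, floored at 0.
#' @export
apply_response <- function(x_0, g, delta) {
  if (any(x_0 <= 0)) stopf("invalid baseline: x_0 must be > 0")
  stopifnot(inherits(g, "response_function"))
  floor0(x_0 * (1 + predict(g, delta)), "response value")
}

#' Split an actual fertility series into increasing and decreasing terms
#'
#' The observed total fertility rate of an industrial country typically rises
#' to a mid-1960s peak and declines thereafter, which contradicts a purely
#' income-driven (Malthusian) fertility mechanism.  To serve both model
#' variants the actual series is decomposed into a linearly increasing
#' "Malthusian" term -- the affine extension of the line through the first two
#' observations -- and a residual term, `actual - malthusian`, which captures
#' the decline.  The reconstruction `malthusian + residual == actual` holds
#' exactly by construction.
#'
#' @param actual Numeric series of annual fertility rates (births/woman/yr),
#'   length >= 2, strictly increasing between the first two observations.
#' @param years Optional calendar years (defaults to an index).
#' @return A `fertility_decomposition`: list with `years`, `actual`,
#'   `malthusian`, `residual`.
#' @export
split_fertility <- function(actual, years = seq_along(actual)) {
  actual <- as.numeric(actual)
  n <- length(actual)
  if (n < 2L) stopf("fertility series must have length >= 2")
  if (length(years) != n) stopf("years and actual must have equal length")
  if (!(actual[2L] > actual[1L]))
    stopf("configuration error: first two observations must be strictly increasing")
  slope <- (actual[2L] - actual[1L]) / (years[2L] - years[1L])
  malthusian <- actual[1L] + slope * (years - years[1L])
  structure(list(years = years, actual = actual,
                 malthusian = malthusian, residual = actual - malthusian),
            class = "fertility_decomposition")
}

#' @export
print.fertility_decomposition <- function(x, ...) {
  cat(sprintf("fertility decomposition over %d years (%s-%s)\n",
              length(x$years), x$years[1L], x$years[length(x$years)]))
  cat(sprintf("  malthusian term: %.3f + %.4f per year\n", x$malthusian[1L],
              (x$malthusian[2L] - x$malthusian[1L]) / (x$years[2L] - x$years[1L])))
  cat(sprintf("  residual range: [%.3f, %.3f]\n",
              min(x$residual), max(x$residual)))
  invisible(x)
}

#' Area-weighted reference product
#'
#' National statistics report yields and prices per crop culture; the model
#' works with one representative product per land class, obtained by weighting
#' component yields and prices by their relative area shares.
#'
#' @param components Data frame with columns `name`, `area_share`, `yield`,
#'   `price`.  Shares must be non-negative and sum to 1 (tolerance 1e-9).
#' @return Named numeric vector `c(yield = , price = )`.
#' @export
weighted_reference <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("area_share", "yield", "price") %in% names(components)))
  s <- components$area_share
  if (any(s < 0) || abs(sum(s) - 1) > 1e-9)
    stopf("share normalization error: area shares must be >= 0 and sum to 1")
  c(yield = sum(s * components$yield), price = sum(s * components$price))
}

#' Fill gaps in an annual series
#'
#' Linear interpolation inside gaps; gaps at either edge are filled with the
#' nearest observed value (constant extension, matching the treatment of price
#' series that begin after the simulation start).
#'
#' @param years Calendar years of the observations.
#' @param values Observed values (may contain `NA`).
#' @param full_years Years the completed series must cover
#'   (default `min(years):max(years)`).
#' @return Data frame with columns `year`, `value`, no missing entries.
#' @export
interpolate_gaps <- function(years, values, full_years = NULL) {
  keep <- is.finite(values)
  years <- years[keep]; values <- values[keep]
  if (length(years) == 0L) stopf("empty series: nothing to interpolate")
  if (is.null(full_years)) full_years <- seq(min(years), max(years))
  if (length(years) == 1L) {
    out <- rep(values, length(full_years))
  } else {
    out <- stats::approx(years, values, xout = full_years, rule = 2)$y
  }
  data.frame(year = full_years, value = out)
}
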