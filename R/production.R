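# Livestock, production and the open-economy income account.
#
# Cattle are fed from grassland and pigs from fodder cropland; legal
# stocking-density caps bind herd sizes to those land classes.  Half the
# cattle stock is dairy, half meat.  The entire crop harvest is sold, fodder
# and grass harvests are feed and carry no revenue; agricultural income is
# earned anew each year from crops, milk, beef, pork and wood at exogenous
# world-market prices.

#' One annual livestock update
#'
#' `stock(t+1) = min(stock * (1 + fertility - slaughter), cap * land)`.
#'
#' @param stock Head count (cattle or pigs).
#' @param land Feed-supplying land area (grassland for cattle, fodder
#'   cropland for pigs), ha.
#' @param fertility,slaughter Annual rates in \[0, 1\].
#' @param cap Stocking-density cap (head/ha).
#' @return Updated head count.
#' @export
livestock_step <- function(stock, land, fertility, slaughter, cap) {
  stopifnot(stock >= 0, land >= 0, cap >= 0,
            fertility >= 0, fertility <= 1, slaughter >= 0, slaughter <= 1)
  min(stock * (1 + fertility - slaughter), cap * land)
}

#' Annual milk production
#'
#' Half the cattle stock is dairy.  Output per cow responds to the ratio of
#' grass to fodder-crop harvest through the saturating anchor-normalized
#' factor `h(r) = 2 r / (r + r_0)` (monotone increasing, `h(r_0) = 1`), and
#' positively to technology.
#'
#' @param cattle Head count.
#' @param grass_t,fodder_t Grass and fodder-crop harvests (t).
#' @param ratio_0 Base-year grass:fodder harvest ratio (anchor).
#' @param base_milk Base-year milk output per dairy cow (t/head/yr).
#' @param tech_delta Relative technology delta.
#' @param g_milk A [response_function()] with non-negative slope.
#' @return Milk output (t/yr), floored at 0.
#' @export
milk_production <- function(cattle, grass_t, fodder_t, ratio_0, base_milk,
                            tech_delta, g_milk) {
  stopifnot(cattle >= 0, base_milk >= 0, ratio_0 > 0,
            inherits(g_milk, "response_function"))
  if (cattle == 0) return(0)
  r <- if (fodder_t > 0) grass_t / fodder_t else ratio_0
  h <- 2 * r / (r + ratio_0)
  floor0((cattle / 2) * base_milk * h * (1 + predict(g_milk, tech_delta)),
         "milk output")
}

#' Annual round-wood production
#'
#' `workers * per_worker_0 * (1 + g_wood(tech_delta))`, floored at 0; labour
#' productivity in forestry rises with technology.
#'
#' @param workers Forestry workers.
#' @param per_worker_0 Base-year output per worker (m3/person/yr).
#' @param tech_delta Relative technology delta.
#' @param g_wood A [response_function()].
#' @return Wood output (m3/yr).
#' @export
wood_production <- function(workers, per_worker_0, tech_delta, g_wood) {
  stopifnot(workers >= 0, per_worker_0 >= 0,
            inherits(g_wood, "response_function"))
  floor0(workers * per_worker_0 * (1 + predict(g_wood, tech_delta)),
         "wood output")
}

#' Agricultural income account
#'
#' Income is the price-weighted sum over the five monetized products --
#' crops, milk, beef, pork, wood; fodder and grass harvests are feed and
#' contribute nothing.  Per-worker income is `NA` when the agricultural
#' labour force is 0.
#'
#' @param quantities Named vector `c(crops, milk, beef, pork, wood)` in t
#'   (wood in m3).
#' @param prices Named vector over the same products (currency per unit).
#' @param ag_labour Agricultural workers.
#' @return A `production_account` list: `quantities`, `prices`, `income`,
#'   `income_per_worker`.
#' @export
agricultural_income <- function(quantities, prices, ag_labour) {
  products <- c("crops", "milk", "beef", "pork", "wood")
  stopifnot(all(products %in% names(quantities)),
            all(products %in% names(prices)),
            all(quantities[products] >= 0), all(prices[products] >= 0),
            ag_labour >= 0)
  income <- sum(quantities[products] * prices[products])
  structure(list(quantities = quantities[products], prices = prices[products],
                 income = income,
                 income_per_worker = if (ag_labour > 0) income / ag_labour
                                     else NA_real_),
            class = "production_account")
}
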