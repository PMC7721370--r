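# Small internal helpers shared across modules.

#' Clip a numeric vector to a range
#' @noRd
clip <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

#' Floor at zero, warning when the floor bites
#'
#' Negative areas, populations or harvests are physically meaningless; the
#' response-function device can nonetheless produce them under strong backward
#' development, so they are floored with a warning rather than an error.
#' @noRd
floor0 <- function(x, what = "quantity") {
  if (any(x < 0, na.rm = TRUE)) {
    warning(sprintf("%s fell below 0 and was floored", what), call. = FALSE)
    x <- pmax(x, 0)
  }
  x
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
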