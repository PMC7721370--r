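# The recorded trajectory class and its methods.

new_sd_trajectory <- function(df, config, init, driver_seed = NULL) {
  attr(df, "meta") <- list(variant = config$variant,
                           scenario = config$scenario,
                           seed = config$seed,
                           driver_seed = driver_seed,
                           config_hash = config_hash(config),
                           total_area_ha = init$total_area_ha)
  attr(df, "config") <- config
  class(df) <- c("sd_trajectory", "data.frame")
  df
}

#' Re-validate module invariants on a recorded trajectory
#'
#' Checks, on every record: exact land-area conservation, forest
#' monotonicity, the population bookkeeping identity
#' `total(t+1) - total(t) = births - deaths - emigrants`, and the livestock
#' stocking caps.
#'
#' @param traj An `sd_trajectory`.
#' @return `TRUE` invisibly, or an error naming the violated invariant.
#' @export
validate_trajectory <- function(traj) {
  stopifnot(inherits(traj, "sd_trajectory"))
  meta <- attr(traj, "meta")
  cfg <- attr(traj, "config")
  total <- traj$crops_ha + traj$fodder_crops_ha + traj$grassland_ha +
    traj$intermediate_ha + traj$forest_ha
  if (any(abs(total - meta$total_area_ha) > 1e-6 * meta$total_area_ha))
    stopf("area conservation violated (max drift %.3g ha)",
          max(abs(total - meta$total_area_ha)))
  if (any(diff(traj$forest_ha) < -1e-9))
    stopf("forest monotonicity violated")
  dtot <- diff(traj$population_total)
  net <- (traj$births - traj$deaths - traj$emigrants)[-1L]
  if (any(abs(dtot - net) > 1e-6))
    stopf("population bookkeeping identity violated (max error %.3g)",
          max(abs(dtot - net)))
  kc <- cfg$production$kappa_cattle
  kp <- cfg$production$kappa_pigs
  if (any(traj$cattle > kc * traj$grassland_ha + 1e-6))
    stopf("cattle stocking cap violated")
  if (any(traj$pigs > kp * traj$fodder_crops_ha + 1e-6))
    stopf("pig stocking cap violated")
  invisible(TRUE)
}

#' @export
print.sd_trajectory <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("%s-model trajectory, scenario %s, %d-%d (%d records)\n",
              m$variant, m$scenario, min(x$year), max(x$year), nrow(x)))
  n <- nrow(x)
  cat(sprintf("  population %s -> %s; forest %.1f%% -> %.1f%%\n",
              format(round(x$population_total[1L]), big.mark = ","),
              format(round(x$population_total[n]), big.mark = ","),
              x$forest_share[1L], x$forest_share[n]))
  invisible(x)
}

#' @export
summary.sd_trajectory <- function(object, ...) {
  m <- attr(object, "meta")
  n <- nrow(object)
  out <- list(
    meta = m,
    years = range(object$year),
    population = c(start = object$population_total[1L],
                   end = object$population_total[n]),
    cohorts_end = c(children = object$children[n],
                    adults = object$adults[n],
                    retirees = object$retirees[n]),
    land_shares_end = c(forest = object$forest_share[n],
                        cropland = object$cropland_share[n],
                        grassland = object$grassland_share[n]),
    mean_migration_rate = mean(object$migration_rate[-1L]),
    final_income_per_ag_worker = object$income_per_ag_worker[n])
  class(out) <- "summary.sd_trajectory"
  out
}

#' @export
print.summary.sd_trajectory <- function(x, ...) {
  cat(sprintf("%s-model / %s, %d-%d\n", x$meta$variant, x$meta$scenario,
              x$years[1L], x$years[2L]))
  cat(sprintf("  population: %s -> %s\n",
              format(round(x$population[1L]), big.mark = ","),
              format(round(x$population[2L]), big.mark = ",")))
  cat(sprintf("  final cohorts: %s children, %s adults, %s retirees\n",
              format(round(x$cohorts_end[1L]), big.mark = ","),
              format(round(x$cohorts_end[2L]), big.mark = ","),
              format(round(x$cohorts_end[3L]), big.mark = ",")))
  cat(sprintf("  final land shares: forest %.1f%%, cropland %.1f%%, grassland %.1f%%\n",
              x$land_shares_end[1L], x$land_shares_end[2L],
              x$land_shares_end[3L]))
  cat(sprintf("  mean out-migration rate: %.2f%%/yr\n",
              100 * x$mean_migration_rate))
  invisible(x)
}

#' @export
as.data.frame.sd_trajectory <- function(x, ...) {
  attr(x, "meta") <- NULL
  attr(x, "config") <- NULL
  class(x) <- "data.frame"
  x
}

#' Plot a trajectory
#'
#' Base-graphics panels: total population with cohorts, and land-class
#' shares (% of total area).
#'
#' @param x An `sd_trajectory`.
#' @param which `"population"`, `"land"` or `"both"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sd_trajectory <- function(x, which = c("both", "population", "land"),
                               ...) {
  which <- match.arg(which)
  m <- attr(x, "meta")
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("both", "population")) {
    graphics::matplot(x$year,
                      cbind(x$population_total, x$children, x$adults,
                            x$retirees),
                      type = "l", lty = 1, lwd = c(2, 1, 1, 1),
                      col = c("black", "steelblue", "darkgreen", "firebrick"),
                      xlab = "year", ylab = "persons",
                      main = sprintf("%s-%s population", m$variant,
                                     m$scenario), ...)
    graphics::legend("topleft", c("total", "children", "adults", "retirees"),
                     lty = 1, lwd = c(2, 1, 1, 1),
                     col = c("black", "steelblue", "darkgreen", "firebrick"),
                     bty = "n", cex = 0.8)
  }
  if (which %in% c("both", "land")) {
    graphics::matplot(x$year,
                      cbind(x$forest_share, x$grassland_share,
                            x$cropland_share),
                      type = "l", lty = 1,
                      col = c("darkgreen", "goldenrod", "sienna"),
                      xlab = "year", ylab = "% of total area",
                      main = sprintf("%s-%s land shares", m$variant,
                                     m$scenario), ...)
    graphics::legend("right", c("forest", "grassland", "cropland"),
                     lty = 1, col = c("darkgreen", "goldenrod", "sienna"),
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Write / read a trajectory as tidy CSV
#'
#' Long format: `year`, `variable`, `value`, plus metadata columns `variant`
#' and `scenario` repeated on every row.
#'
#' @param traj An `sd_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  m <- attr(traj, "meta")
  df <- as.data.frame(traj)
  vars <- setdiff(names(df), "year")
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(year = df$year, variable = v, value = df[[v]],
               variant = m$variant, scenario = m$scenario)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  wide <- stats::reshape(long[c("year", "variable", "value")],
                         idvar = "year", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$year), ]
  rownames(wide) <- NULL
  attr(wide, "meta") <- list(variant = long$variant[1L],
                             scenario = long$scenario[1L])
  class(wide) <- c("sd_trajectory", "data.frame")
  wide
}
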