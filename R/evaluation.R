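# Trajectory evaluation against an empirical (or pseudo-empirical) record.
#
# The comparison protocol divides the horizon into three periods (1960-80,
# 1980-2000, 2000-2010) and reports, per variable and run, the signed
# endpoint deviation 100 * (model - empirical) / empirical at the last year
# both series share within the period.

#' Default period split
#'
#' @return List of three `c(start, end)` calendar-year windows.
#' @export
default_periods <- function() {
  list("1960-1980" = c(1960, 1980),
       "1980-2000" = c(1980, 2000),
       "2000-2010" = c(2000, 2010))
}

#' Signed relative deviation of model from empirical at one year
#'
#' `100 * (model - empirical) / empirical`.  Note the metric is asymmetric
#' in magnitude: a 2x inflation reports +100% while the corresponding 0.5x
#' deflation reports -50%.
#'
#' @param model,empirical Data frames with columns `year` and `value`, both
#'   defined at `year`.
#' @param year Evaluation year.
#' @return Signed percent deviation; `NA` when the empirical value is 0.
#' @export
relative_deviation <- function(model, empirical, year) {
  mv <- model$value[model$year == year]
  ev <- empirical$value[empirical$year == year]
  if (length(mv) != 1L || length(ev) != 1L)
    stopf("both series must be defined at year %s", year)
  if (ev == 0) return(NA_real_)
  100 * (mv - ev) / ev
}

# model trajectory column holding each evaluation variable
EVAL_VARS <- c(population_total = "population_total",
               children = "children", adults = "adults",
               retirees = "retirees", forest_share = "forest_share",
               cropland_share = "cropland_share",
               grassland_share = "grassland_share")

#' Period-wise deviation report for a run matrix
#'
#' One row per (variable, run, period): the endpoint deviation at the last
#' year within the period present in both the trajectory and the empirical
#' bundle, plus a heuristic fit verdict.  Missing variables are flagged, not
#' dropped.
#'
#' @param runs An `sd_trajectory_matrix` (or named list of `sd_trajectory`).
#' @param empirical Data frame with column `year` and one column per
#'   evaluation variable (as from [generate_empirical()]).
#' @param periods Period split, default [default_periods()].
#' @param variables Evaluation variables (default: total population, the
#'   three cohorts, and the forest/cropland/grassland shares).
#' @param cutoffs Verdict cutoffs on `|deviation|` in percent:
#'   `c(good, moderate)`; beyond the second lies "notable misfit".  The
#'   verdict column is heuristic.
#' @return A `deviation_report` data frame with columns `variable`,
#'   `variant`, `scenario`, `period`, `year`, `deviation_pct`, `verdict`.
#' @export
period_summary <- function(runs, empirical, periods = default_periods(),
                           variables = names(EVAL_VARS),
                           cutoffs = c(5, 20)) {
  stopifnot(is.list(runs), length(runs) >= 1L, "year" %in% names(empirical))
  rows <- list()
  for (rn in names(runs)) {
    traj <- runs[[rn]]
    m <- attr(traj, "meta")
    for (v in variables) {
      col <- if (v %in% names(EVAL_VARS)) EVAL_VARS[[v]] else v
      have <- col %in% names(traj) && v %in% names(empirical)
      for (pn in names(periods)) {
        p <- periods[[pn]]
        yr <- if (have)
          max(intersect(traj$year[traj$year >= p[1L] & traj$year <= p[2L]],
                        empirical$year), -Inf) else -Inf
        if (!have || !is.finite(yr)) {
          rows[[length(rows) + 1L]] <- data.frame(
            variable = v, variant = m$variant, scenario = m$scenario,
            period = pn, year = NA_integer_, deviation_pct = NA_real_,
            verdict = "missing")
          next
        }
        dev <- relative_deviation(
          data.frame(year = traj$year, value = traj[[col]]),
          data.frame(year = empirical$year, value = empirical[[v]]), yr)
        verdict <- if (is.na(dev)) "missing"
          else if (abs(dev) <= cutoffs[1L]) "good fit"
          else if (abs(dev) <= cutoffs[2L]) "moderate fit"
          else "notable misfit"
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, variant = m$variant, scenario = m$scenario,
          period = pn, year = yr, deviation_pct = dev, verdict = verdict)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("deviation_report", "data.frame")
  out
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("deviation report: %d rows (%d runs x %d variables x %d periods)\n",
              nrow(x), length(unique(paste(x$variant, x$scenario))),
              length(unique(x$variable)), length(unique(x$period))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}
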