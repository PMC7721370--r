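# Land-class stock-flow accounting.
#
# Five classes: crops, fodder crops and grassland (the cultivated area),
# intermediate area (temporarily uncultivated, re-cultivable next year) and
# forest.  Total area is fixed.  Each year cultivation shortfalls move land
# into the intermediate pool, expansion re-cultivates from it, and 1/30 of
# the remaining intermediate stock succeeds irreversibly to forest: forestry
# law forbids any flow out of forest.

LAND_CLASSES <- c("crops", "fodder_crops", "grassland", "intermediate", "forest")
CULTIVATED <- c("crops", "fodder_crops", "grassland")

#' Cultivable land per farmer
#'
#' Capacity is the binding minimum of the land actually available per farmer
#' and the base-year capacity augmented by technological progress:
#' `min(available_ag / farmers, cap_0 * (1 + g_cap(tech_delta)))`.
#'
#' @param available_ag Agricultural land available (cultivated +
#'   intermediate, ha).
#' @param farmers Agricultural workers; if 0, capacity is 0 and no land is
#'   cultivated that year.
#' @param cap_0 Base-year capacity (ha/person).
#' @param tech_delta Relative technology delta.
#' @param g_cap A [response_function()] (non-negative slope: technology
#'   raises the workable area).
#' @return Capacity in ha/person.
#' @export
farmer_capacity <- function(available_ag, farmers, cap_0, tech_delta, g_cap) {
  stopifnot(available_ag >= 0, cap_0 > 0, inherits(g_cap, "response_function"))
  if (farmers <= 0) return(0)
  min(available_ag / farmers,
      max(cap_0 * (1 + predict(g_cap, tech_delta)), 0))
}

#' Allocate the cultivated area among land types
#'
#' Total cultivation is `farmers * capacity`, capped by the available
#' agricultural land.  The split shifts with technology: the crop and fodder
#' shares are the base-year shares scaled by a positively sloped preference
#' response, grassland takes the complement.
#'
#' @param farmers,capacity Workers and per-worker capacity (ha/person).
#' @param available_ag Agricultural land available (ha).
#' @param tech_delta Relative technology delta.
#' @param shares_0 Named base-year shares `c(crops, fodder_crops, grassland)`
#'   summing to 1.
#' @param g_pref A [response_function()] with non-negative slope.
#' @return A `cultivation_plan`: list with `targets` (named ha per cultivated
#'   class) and `total`.
#' @export
allocate_cultivated <- function(farmers, capacity, available_ag, tech_delta,
                                shares_0, g_pref) {
  stopifnot(capacity >= 0, farmers >= 0, available_ag >= 0,
            all(CULTIVATED %in% names(shares_0)),
            inherits(g_pref, "response_function"))
  if (abs(sum(shares_0[CULTIVATED]) - 1) > 1e-9)
    stopf("cultivated shares must sum to 1")
  if (g_pref$slope < 0)
    stopf("preference response must favour crops under progress (slope >= 0)")
  total <- min(farmers * capacity, available_ag)
  scale <- 1 + predict(g_pref, tech_delta)
  s_crop <- clip(shares_0[["crops"]] * scale, 0, 1)
  s_fodder <- clip(shares_0[["fodder_crops"]] * scale, 0, 1 - s_crop)
  s_grass <- 1 - s_crop - s_fodder
  targets <- total * c(crops = s_crop, fodder_crops = s_fodder,
                       grassland = s_grass)
  structure(list(targets = targets, total = total),
            class = "cultivation_plan")
}

#' One annual land-use step
#'
#' Order of flows: (i) cultivated classes move to the plan targets, with
#' shortfalls released into the intermediate pool and expansion re-cultivated
#' from it; (ii) 1/30 of the post-transfer intermediate stock succeeds to
#' forest.  Forest never decreases and total area is conserved exactly.  The
#' realized inter-class flow matrix is attached as attribute `"flows"`
#' (rows = from, columns = to) for structural audits.
#'
#' @param state Named vector over
#'   `c("crops","fodder_crops","grassland","intermediate","forest")`, ha.
#' @param plan A `cultivation_plan` from [allocate_cultivated()].
#' @param succession_rate Fraction of intermediate land converting to forest
#'   each year (default 1/30).
#' @return Updated land state (same names), with the flow matrix attached.
#' @export
step_land <- function(state, plan, succession_rate = 1 / 30) {
  stopifnot(all(LAND_CLASSES %in% names(state)), all(state >= 0),
            inherits(plan, "cultivation_plan"),
            succession_rate >= 0, succession_rate <= 1)
  total_area <- sum(state[LAND_CLASSES])
  available <- sum(state[CULTIVATED]) + state[["intermediate"]]
  targets <- plan$targets
  if (sum(targets) > available + 1e-9) {
    warning("cultivation plan exceeds available agricultural land; truncated",
            call. = FALSE)
    targets <- targets * available / sum(targets)
  }
  flows <- matrix(0, 5, 5, dimnames = list(LAND_CLASSES, LAND_CLASSES))
  d <- targets[CULTIVATED] - state[CULTIVATED]
  flows[cbind(CULTIVATED, "intermediate")] <- pmax(-d, 0)  # abandonment
  flows[cbind("intermediate", CULTIVATED)] <- pmax(d, 0)   # re-cultivation
  intermediate <- available - sum(targets)
  gain <- succession_rate * intermediate                   # succession on the
  flows["intermediate", "forest"] <- gain                  # post-transfer stock
  new <- c(targets[CULTIVATED],
           intermediate = unname(intermediate - gain),
           forest = unname(state[["forest"]] + gain))
  # conservation guard: park float drift (if any) in the intermediate pool
  drift <- total_area - sum(new)
  if (abs(drift) > 1e-6 * total_area)
    stopf("land accounting lost %.3g ha", drift)
  new[["intermediate"]] <- max(new[["intermediate"]] + drift, 0)
  attr(new, "flows") <- flows
  new
}

#' Audit the land transition structure
#'
#' Checks, on the flow matrix recorded by [step_land()], that no pathway
#' leaves the forest class.
#'
#' @param flows A flow matrix as attached by [step_land()].
#' @return `TRUE` if forest has no outgoing flow; otherwise an error.
#' @export
audit_land_flows <- function(flows) {
  out <- flows["forest", setdiff(colnames(flows), "forest")]
  if (any(out != 0)) stopf("illegal flow out of forest")
  TRUE
}
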