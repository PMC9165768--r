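# Four-fleet partition and model calibration.
#
# Vessels are partitioned by management tier x reform-affectedness into the
# fleets M-A, M-U, OA-A, OA-U. Base-year aggregates (harvest, effort,
# revenue, effective subsidies) come from summing component vessels;
# catchability q and cost coefficient alpha are calibrated so that base-year
# harvest and the zero-profit condition are reproduced exactly.

FLEET_LABELS <- c("M-U", "M-A", "OA-U", "OA-A")

#' Label each vessel with its model fleet
#'
#' Crosses the management tier (from [assign_management_tier()]) with the
#' reform-affected flag (from [apply_proposal()] or
#' [select_affected_vessels()]) into the four fleet labels `M-A`, `M-U`,
#' `OA-A`, `OA-U`. The partition is exhaustive and disjoint.
#'
#' @param vessels A vessel database with `management_tier` and `affected`
#'   columns.
#' @return `vessels` with a `fleet` column.
#' @export
partition_fleets <- function(vessels) {
  for (col in c("management_tier", "affected")) {
    if (!col %in% names(vessels))
      stop("partition_fleets needs a '", col, "' column; ",
           "run assign_management_tier / the policy engine first")
  }
  vessels$fleet <- paste0(
    ifelse(vessels$management_tier == "managed", "M", "OA"),
    ifelse(vessels$affected, "-A", "-U"))
  vessels
}

#' Base-year aggregates of the four fleets
#'
#' Sums the component vessels of each fleet: base-year harvest `h0` (t),
#' effort `e0` (kWh), revenue, and nominal/effective subsidies; the subsidy
#' rate `s0` is effective subsidies per unit effort (USD/kWh). Fleets with no
#' vessels carry zeros and are marked inert. Effective subsidies enter the
#' model, because the multiplier normalization exists precisely to put
#' subsidy types on an effort-effect scale.
#'
#' @param vessels A partitioned vessel database ([partition_fleets()]) with
#'   allocations and, if a proposal was applied, removal columns.
#' @param weights Effective-subsidy multipliers used if
#'   `effective_subsidy_usd` is not already present.
#' @return Data.frame with one row per fleet label.
#' @export
aggregate_fleets <- function(vessels, weights = NULL) {
  if (!"fleet" %in% names(vessels)) stop("vessels must carry a 'fleet' column")
  sub_cols <- subsidy_columns(vessels)
  if (!"effective_subsidy_usd" %in% names(vessels)) {
    types <- subsidy_col_type(sub_cols)
    if (is.null(weights)) weights <- default_effective_weights(types)
    amounts <- as.matrix(vessels[, sub_cols, drop = FALSE])
    vessels$effective_subsidy_usd <- as.numeric(amounts %*% weights[types])
  }
  if (!"removed_effective_usd" %in% names(vessels))
    vessels$removed_effective_usd <- 0
  tot_eff <- vessel_total_effort(vessels)
  agg_one <- function(lbl) {
    sel <- vessels$fleet == lbl
    e0 <- sum(tot_eff[sel])
    sub_eff <- sum(vessels$effective_subsidy_usd[sel])
    removed <- sum(vessels$removed_effective_usd[sel])
    if (e0 <= 0 && sub_eff > 0)
      stop("fleet ", lbl, " has subsidies but zero effort")
    data.frame(fleet = lbl,
               managed = startsWith(lbl, "M"),
               affected = endsWith(lbl, "-A"),
               n_vessels = sum(sel),
               h0 = sum(vessels$catch_t[sel]),
               e0 = e0,
               revenue0 = sum(vessels$revenue_usd[sel]),
               subsidy_eff0_usd = sub_eff,
               removed_eff_usd = removed,
               s0 = if (e0 > 0) sub_eff / e0 else 0,
               s_reformed = if (e0 > 0) max(0, sub_eff - removed) / e0 else 0,
               inert = e0 <= 0,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(FLEET_LABELS, agg_one))
  rownames(out) <- NULL
  out
}

#' Population growth rate from MSY, K and the production-curve shape
#'
#' For the asymmetric surplus-production (Pella-Tomlinson) model, the
#' intrinsic growth rate is `g = (MSY / K) * (phi + 1)^(1 / phi)`, so the
#' maximum of the production curve equals MSY.
#'
#' @param MSY Maximum sustainable yield (tonnes/yr, > 0).
#' @param K Carrying capacity (tonnes, > 0).
#' @param phi Production-curve asymmetry (> 0).
#' @return Growth rate g (1/yr).
#' @export
#' @examples
#' growth_rate_from_msy(100, 1000, 1)  # 0.2
growth_rate_from_msy <- function(MSY, K, phi) {
  if (any(MSY < 0)) stop("MSY must be >= 0")
  if (any(K <= 0) || any(phi <= 0)) stop("K and phi must be > 0")
  (MSY / K) * (phi + 1)^(1 / phi)
}

#' Fleet catchability from base-year harvest, biomass and effort
#'
#' `q = h0 / (b0 * e0)`, so that the harvest equation reproduces the
#' base-year harvest exactly at base-year biomass and effort.
#'
#' @param h0 Base-year harvest of the fleet (tonnes, >= 0).
#' @param b0 Base-year global stock biomass (tonnes, > 0).
#' @param e0 Base-year effort of the fleet (kWh, > 0).
#' @return Catchability q (per kWh).
#' @export
calibrate_catchability <- function(h0, b0, e0) {
  if (any(b0 <= 0) || any(e0 <= 0))
    stop("b0 and e0 must be > 0 to calibrate catchability")
  h0 / (b0 * e0)
}

#' Demand constant from the base-year price-harvest pair
#'
#' For the constant-elasticity demand curve, `delta = h0 * p0^epsilon`;
#' evaluating the inverse demand at `h0` then returns `p0` exactly.
#'
#' @param h0 Base-year total harvest (tonnes, > 0).
#' @param p0 Base-year price (USD/tonne, > 0).
#' @param epsilon Demand elasticity (non-zero; negative for downward-sloping
#'   demand).
#' @return The demand constant delta.
#' @export
calibrate_demand_constant <- function(h0, p0, epsilon) {
  if (any(h0 <= 0) || any(p0 <= 0)) stop("h0 and p0 must be > 0")
  if (any(epsilon == 0)) stop("epsilon must be non-zero")
  h0 * p0^epsilon
}

#' Fleet cost coefficient under the zero-profit assumption
#'
#' Assuming base-year profits are zero -- revenue plus subsidies exactly
#' cover costs -- the cost coefficient is
#' `alpha = (p0 * h0 + s0 * e0) / e0^beta`. Solving for alpha this way
#' captures the role subsidies play in artificially lowering operating costs.
#'
#' @param p0 Base-year price (USD/tonne).
#' @param h0 Fleet base-year harvest (tonnes).
#' @param s0 Fleet base-year effective subsidy rate (USD/kWh).
#' @param e0 Fleet base-year effort (kWh, > 0).
#' @param beta Cost-curve exponent (>= 1).
#' @return Cost coefficient alpha (USD per kWh^beta).
#' @export
#' @examples
#' calibrate_cost_coefficient(1000, 100, 0.05, 1e6, beta = 1)  # 0.15
calibrate_cost_coefficient <- function(p0, h0, s0, e0, beta) {
  if (any(e0 <= 0)) stop("e0 must be > 0 to calibrate the cost coefficient")
  if (any(beta <= 0)) stop("beta must be > 0")
  (p0 * h0 + s0 * e0) / e0^beta
}

#' Aggregate and calibrate the four fleets
#'
#' Combines [aggregate_fleets()] with the per-fleet calibrations: `q` from
#' base-year harvest, global biomass and effort, and `alpha` from the
#' zero-profit condition. Inert (empty) fleets get `q = alpha = 0` and are
#' carried through the projection with zero effort.
#'
#' @param vessels Partitioned, allocated vessel database.
#' @param params A [model_params()] object supplying `b0`, `p0`, `beta`.
#' @param weights Effective-subsidy multipliers (see [aggregate_fleets()]).
#' @return Data.frame of class `fleet_table`, one row per fleet with
#'   aggregates and coefficients.
#' @export
calibrate_fleets <- function(vessels, params, weights = NULL) {
  stopifnot(inherits(params, "model_params"))
  fleets <- aggregate_fleets(vessels, weights)
  fleets$q <- ifelse(fleets$e0 > 0,
                     calibrate_catchability(fleets$h0, params$b0,
                                            pmax(fleets$e0, 1e-300)),
                     0)
  fleets$alpha <- ifelse(fleets$e0 > 0,
                         calibrate_cost_coefficient(params$p0, fleets$h0,
                                                    fleets$s0,
                                                    pmax(fleets$e0, 1e-300),
                                                    params$beta),
                         0)
  class(fleets) <- c("fleet_table", "data.frame")
  fleets
}

#' Write a calibration summary as JSON
#'
#' Records the per-fleet aggregates and coefficients, plus the global growth
#' rate and demand constant, for audit.
#'
#' @param fleets A [calibrate_fleets()] table.
#' @param params A [model_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_summary <- function(fleets, params, path) {
  h0 <- sum(fleets$h0)
  summary <- list(
    fleets = fleets,
    global = list(g = params$g, K = params$K, b0 = params$b0,
                  MSY = params$MSY, phi = params$phi,
                  h0_total = h0, p0 = params$p0,
                  delta = calibrate_demand_constant(max(h0, 1e-300),
                                                    params$p0, params$epsilon)))
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
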