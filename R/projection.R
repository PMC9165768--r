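# Annual bioeconomic projection.
#
# Single global Pella-Tomlinson stock shared by four fleets. Within a year
# the update order is: harvest -> price -> costs/profits -> biomass ->
# effort; the biomass update uses the current year's harvest and the effort
# update the current year's profit. Open-access fleets adjust effort at
# speed eta, managed fleets at speed omega (omega << eta).

#' Global bioeconomic model parameters
#'
#' Validated container for the biological and economic parameters of the
#' projection. Supply either `MSY` or `g` (the other is derived through the
#' surplus-production identity `g = (MSY/K) (phi+1)^{1/phi}`); if both are
#' given they must agree to 1e-6 relative. The demand constant `delta` is
#' normally left `NULL` and calibrated from the base-year harvest when a
#' projection runs.
#'
#' @param phi Production-curve asymmetry (> 0); 0.188 puts the most
#'   productive biomass at 0.4 K.
#' @param K Carrying capacity of the global stock (tonnes, > 0).
#' @param b0 Base-year biomass (tonnes, 0 < b0 <= K).
#' @param MSY Maximum sustainable yield (tonnes/yr).
#' @param g Intrinsic growth rate (1/yr).
#' @param epsilon Demand elasticity; must be negative (downward-sloping
#'   demand), so price falls when harvest rises.
#' @param p0 Base-year ex-vessel price (USD/tonne, > 0).
#' @param delta Demand constant; usually calibrated, see
#'   [calibrate_demand_constant()].
#' @param beta Cost-curve exponent (>= 1).
#' @param eta Open-access effort-adjustment speed (kWh per USD of profit).
#' @param omega Managed effort-adjustment speed; requires
#'   `eta > omega >= 0`.
#' @param base_year First simulated year (default 2018).
#' @param horizon_year Last simulated year (default 2050).
#' @return An object of class `model_params`.
#' @export
#' @examples
#' model_params(phi = 0.188, K = 5e7, b0 = 2.5e7, MSY = 2e6,
#'              epsilon = -1.2, p0 = 1500, beta = 1.3,
#'              eta = 0.2, omega = 0.005)
model_params <- function(phi, K, b0, MSY = NULL, g = NULL, epsilon, p0,
                         delta = NULL, beta, eta, omega,
                         base_year = 2018L, horizon_year = 2050L) {
  if (phi <= 0) stop("model parameter 'phi' must be > 0")
  if (K <= 0) stop("model parameter 'K' must be > 0")
  if (b0 <= 0 || b0 > K) stop("model parameter 'b0' must satisfy 0 < b0 <= K")
  if (is.null(MSY) && is.null(g)) stop("supply MSY or g")
  if (is.null(g)) g <- growth_rate_from_msy(MSY, K, phi)
  if (is.null(MSY)) MSY <- g * K / (phi + 1)^(1 / phi)
  if (abs(g - growth_rate_from_msy(MSY, K, phi)) > 1e-6 * max(g, 1e-12))
    stop("MSY and g are inconsistent with K and phi")
  if (epsilon >= 0)
    stop("model parameter 'epsilon' must be negative (downward-sloping demand)")
  if (p0 <= 0) stop("model parameter 'p0' must be > 0")
  if (beta < 1) stop("model parameter 'beta' must be >= 1")
  if (omega < 0 || eta <= omega)
    stop("effort-adjustment speeds must satisfy eta > omega >= 0")
  if (horizon_year <= base_year) stop("horizon_year must exceed base_year")
  structure(list(phi = phi, K = K, b0 = b0, MSY = MSY, g = g,
                 epsilon = epsilon, p0 = p0, delta = delta, beta = beta,
                 eta = eta, omega = omega,
                 base_year = as.integer(base_year),
                 horizon_year = as.integer(horizon_year)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0("<model_params: phi=%.4g g=%.4g K=%.4g b0=%.4g MSY=%.4g\n",
                     "  epsilon=%.4g p0=%.4g beta=%.4g eta=%.4g omega=%.4g ",
                     "years %d-%d>\n"),
              x$phi, x$g, x$K, x$b0, x$MSY, x$epsilon, x$p0, x$beta, x$eta,
              x$omega, x$base_year, x$horizon_year))
  invisible(x)
}

#' Surplus production of the stock at biomass b
#'
#' The asymmetric logistic production term
#' `((phi + 1) / phi) * g * b * (1 - (b / K)^phi)`, which is zero at b = 0
#' and at carrying capacity and attains its maximum MSY at
#' `b = K (phi + 1)^{-1/phi}`.
#'
#' @param b Biomass (tonnes, >= 0).
#' @param params A [model_params()] object.
#' @return Surplus production (tonnes/yr).
#' @export
surplus_production <- function(b, params) {
  ((params$phi + 1) / params$phi) * params$g * b * (1 - (b / params$K)^params$phi)
}

#' One annual biomass update
#'
#' `b_{t+1} = b_t + surplus_production(b_t) - h_t`, floored at zero so that
#' overharvest cannot drive the stock negative.
#'
#' @param b_t Current biomass (tonnes, >= 0).
#' @param params A [model_params()] object.
#' @param h_t Total harvest in the current year (tonnes, >= 0).
#' @return Next-year biomass (tonnes).
#' @export
surplus_production_step <- function(b_t, params, h_t) {
  if (any(b_t < 0) || any(h_t < 0)) stop("biomass and harvest must be >= 0")
  pmax(0, b_t + surplus_production(b_t, params) - h_t)
}

#' Fleet harvest and total harvest
#'
#' Harvest of fleet j is `h_j = q_j * b_t * e_j`; the total is the sum over
#' fleets.
#'
#' @param q Fleet catchability (per kWh).
#' @param b Current biomass (tonnes).
#' @param e Fleet effort (kWh).
#' @return Harvest (tonnes).
#' @export
fleet_harvest <- function(q, b, e) {
  if (any(q < 0) || any(b < 0) || any(e < 0))
    stop("q, b and e must all be >= 0")
  q * b * e
}

#' @rdname fleet_harvest
#' @param harvests Numeric vector of fleet harvests.
#' @export
total_harvest <- function(harvests) sum(harvests)

#' Price from total harvest (constant-elasticity inverse demand)
#'
#' Evaluates the inverse demand through the calibration identity
#' `p_t = p0 * (h_t / h0)^{1/epsilon}`, with the base-year harvest recovered
#' from the demand constant (`h0 = delta * p0^{-epsilon}`); price decreases
#' in harvest for negative elasticity and returns `p0` exactly at `h0`. Harvests below a small floor (1e-6 of
#' the calibration harvest) are evaluated at the floor to avoid the
#' singularity at zero harvest; a warning is raised when the guard engages.
#'
#' @param h_t Total harvest (tonnes).
#' @param params A [model_params()] object whose `delta` is set.
#' @return Price (USD/tonne).
#' @export
price_from_harvest <- function(h_t, params) {
  if (is.null(params$delta))
    stop("params$delta is not set; calibrate it with calibrate_demand_constant")
  h0 <- params$delta * params$p0^(-params$epsilon)
  floor_h <- 1e-6 * h0
  if (any(h_t < floor_h)) {
    warning("harvest at or below the pricing floor; price evaluated at the floor")
    h_t <- pmax(h_t, floor_h)
  }
  params$p0 * (h_t / h0)^(1 / params$epsilon)
}

#' Fleet fishing costs and profit
#'
#' Costs are `c = alpha * e^beta`; profit is revenue less costs plus
#' subsidies, `pi = p * h - c + s * e`, with `s` the effective subsidy rate
#' in USD/kWh.
#'
#' @param alpha Fleet cost coefficient.
#' @param e Fleet effort (kWh).
#' @param beta Cost-curve exponent.
#' @return `fleet_cost`: cost (USD).
#' @export
fleet_cost <- function(alpha, e, beta) {
  if (any(alpha < 0) || any(e < 0)) stop("alpha and e must be >= 0")
  alpha * e^beta
}

#' @rdname fleet_cost
#' @param p Price (USD/tonne).
#' @param h Fleet harvest (tonnes).
#' @param cost Fleet cost (USD).
#' @param s Effective subsidy rate (USD/kWh).
#' @return `fleet_profit`: profit (USD).
#' @export
fleet_profit <- function(p, h, cost, s, e) {
  p * h - cost + s * e
}

#' Effort adjustment from profit
#'
#' `e_{t+1} = max(0, speed * pi_t + e_t)`: effort enters when profits are
#' positive and exits when negative, at speed `eta` for open-access fleets
#' and the much smaller `omega` for managed fleets (management decouples
#' effort from profit).
#'
#' @param e Current effort (kWh, >= 0).
#' @param profit Current profit (USD).
#' @param speed Adjustment speed (kWh per USD).
#' @return Next-year effort (kWh).
#' @export
#' @examples
#' update_effort(10000, -1000, 2)  # 8000
update_effort <- function(e, profit, speed) {
  if (any(e < 0)) stop("effort must be >= 0")
  if (any(speed < 0)) stop("adjustment speed must be >= 0")
  pmax(0, speed * profit + e)
}

#' Run the annual projection for one scenario
#'
#' Iterates the coupled biomass-harvest-price-profit-effort system from the
#' base year to the horizon year. All four fleets start at their base-year
#' efforts; under `"reform"` the affected fleets carry their post-reform
#' subsidy rates while unaffected fleets retain their original rates, and
#' under `"bau"` every fleet keeps its base-year rate throughout. Should the
#' fleets attempt to harvest more than the stock plus its growth in a year,
#' harvests are scaled down proportionally (preserving fleet shares) before
#' the biomass floor applies. Fishing mortality is reported as
#' `F_t = h_t / b_t`.
#'
#' @param fleets A [calibrate_fleets()] table.
#' @param params A [model_params()] object; if `delta` is `NULL` it is
#'   calibrated from the fleets' total base-year harvest.
#' @param scenario `"bau"` or `"reform"`.
#' @return An object of class `fleet_trajectory`: list with data.frames
#'   `global` (year, biomass, price, harvest, fishing_mortality, revenue,
#'   profit) and `fleet` (year x fleet: effort, harvest, cost, profit,
#'   subsidy_rate), plus the scenario name.
#' @export
run_projection <- function(fleets, params, scenario = c("bau", "reform")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(params, "model_params"))
  needed <- c("fleet", "managed", "e0", "s0", "s_reformed", "q", "alpha")
  missing <- setdiff(needed, names(fleets))
  if (length(missing) > 0L)
    stop("fleet table lacks column(s): ", paste(missing, collapse = ", "))
  if (is.null(params$delta)) {
    h0 <- sum(fleets$h0)
    if (h0 <= 0) stop("cannot calibrate demand: total base-year harvest is 0")
    params$delta <- calibrate_demand_constant(h0, params$p0, params$epsilon)
  }
  years <- params$base_year:params$horizon_year
  nT <- length(years)
  nF <- nrow(fleets)
  s <- if (scenario == "reform") fleets$s_reformed else fleets$s0
  speed <- ifelse(fleets$managed, params$omega, params$eta)

  g_year <- numeric(nT); g_b <- numeric(nT); g_p <- numeric(nT)
  g_h <- numeric(nT); g_F <- numeric(nT); g_rev <- numeric(nT)
  g_pi <- numeric(nT)
  f_eff <- matrix(0, nT, nF); f_h <- matrix(0, nT, nF)
  f_cost <- matrix(0, nT, nF); f_pi <- matrix(0, nT, nF)

  b <- params$b0
  e <- fleets$e0
  for (i in seq_len(nT)) {
    h_j <- fleet_harvest(fleets$q, b, e)
    grow <- surplus_production(b, params)
    h_tot <- sum(h_j)
    avail <- b + grow
    if (h_tot > avail) {           # proportional scale-down, fleet shares kept
      scale <- if (avail > 0) avail / h_tot else 0
      h_j <- h_j * scale
      h_tot <- sum(h_j)
    }
    p <- suppressWarnings(price_from_harvest(h_tot, params))
    cost <- fleet_cost(fleets$alpha, e, params$beta)
    prof <- fleet_profit(p, h_j, cost, s, e)
    state <- c(b, p, h_j, e, prof)
    if (any(!is.finite(state)))
      stop("projection diverged in year ", years[i], ": b=", b, " p=", p,
           " h=", h_tot, " e=[", paste(signif(e, 6), collapse = ", "), "]")
    g_year[i] <- years[i]; g_b[i] <- b; g_p[i] <- p; g_h[i] <- h_tot
    g_F[i] <- if (b > 0) h_tot / b else 0
    g_rev[i] <- p * h_tot; g_pi[i] <- sum(prof)
    f_eff[i, ] <- e; f_h[i, ] <- h_j; f_cost[i, ] <- cost; f_pi[i, ] <- prof
    b <- pmax(0, b + grow - h_tot)
    e <- update_effort(e, prof, speed)
  }

  global <- data.frame(year = g_year, biomass = g_b, price = g_p,
                       harvest = g_h, fishing_mortality = g_F,
                       revenue = g_rev, profit = g_pi)
  fleet_df <- data.frame(
    year = rep(g_year, times = nF),
    fleet = rep(fleets$fleet, each = nT),
    effort = as.numeric(f_eff), harvest = as.numeric(f_h),
    cost = as.numeric(f_cost), profit = as.numeric(f_pi),
    subsidy_rate = rep(s, each = nT),
    stringsAsFactors = FALSE)
  structure(list(global = global, fleet = fleet_df, scenario = scenario,
                 params = params),
            class = "fleet_trajectory")
}

#' @export
print.fleet_trajectory <- function(x, ...) {
  last <- x$global[nrow(x$global), ]
  cat(sprintf("<%s trajectory %d-%d: biomass %.4g t, harvest %.4g t at horizon>\n",
              x$scenario, min(x$global$year), max(x$global$year),
              last$biomass, last$harvest))
  invisible(x)
}

#' Percent changes of a reform scenario against BAU
#'
#' Compares the two trajectories at the horizon year on biomass, total
#' catch, total revenue and fishing mortality:
#' `100 * (reform - bau) / bau`. Metrics with a zero BAU value are reported
#' `NA` with a warning.
#'
#' @param bau,reform [run_projection()] trajectories sharing years/params.
#' @return An object of class `scenario_result`: data.frame with `metric`,
#'   `bau`, `reform`, `pct_change`.
#' @export
compare_scenarios <- function(bau, reform) {
  stopifnot(inherits(bau, "fleet_trajectory"),
            inherits(reform, "fleet_trajectory"))
  if (!identical(bau$global$year, reform$global$year))
    stop("trajectories cover different years")
  bl <- bau$global[nrow(bau$global), ]
  rl <- reform$global[nrow(reform$global), ]
  metrics <- c(biomass = "biomass", catch = "harvest", revenue = "revenue",
               fishing_mortality = "fishing_mortality")
  out <- data.frame(metric = names(metrics),
                    bau = as.numeric(bl[unname(metrics)]),
                    reform = as.numeric(rl[unname(metrics)]),
                    stringsAsFactors = FALSE)
  zero <- out$bau == 0
  if (any(zero))
    warning("BAU value is zero for: ",
            paste(out$metric[zero], collapse = ", "),
            "; percent change undefined")
  out$pct_change <- ifelse(zero, NA_real_,
                           100 * (out$reform - out$bau) / out$bau)
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Change at horizon vs BAU (%):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-18s %+8.3f\n", x$metric[i], x$pct_change[i]))
  invisible(x)
}

#' Write a trajectory as tidy CSV
#'
#' One row per (year, series): the global series plus every fleet series.
#'
#' @param traj A [run_projection()] trajectory.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "fleet_trajectory"))
  g <- traj$global
  glong <- data.frame(year = rep(g$year, 6),
                      fleet = "global",
                      variable = rep(c("biomass", "price", "harvest",
                                       "fishing_mortality", "revenue",
                                       "profit"), each = nrow(g)),
                      value = c(g$biomass, g$price, g$harvest,
                                g$fishing_mortality, g$revenue, g$profit),
                      stringsAsFactors = FALSE)
  f <- traj$fleet
  flong <- do.call(rbind, lapply(
    c("effort", "harvest", "cost", "profit", "subsidy_rate"),
    function(v) data.frame(year = f$year, fleet = f$fleet, variable = v,
                           value = f[[v]], stringsAsFactors = FALSE)))
  out <- rbind(glong, flong)
  out$scenario <- traj$scenario
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
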