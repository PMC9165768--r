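# End-to-end scenario pipeline: allocate -> policy -> partition -> calibrate
# -> project (BAU and reform) -> compare.

#' Run one reform scenario end to end
#'
#' Chains the whole pipeline on raw inputs: computes allocation rates,
#' allocates vessel economics, splits managed/open-access tiers, applies the
#' proposal (disciplines and any cap rule), partitions the four fleets,
#' calibrates the model, runs the BAU and reform projections and compares
#' them at the horizon.
#'
#' @param vessels A vessel database (allocations not yet filled).
#' @param subsidies Country subsidy table.
#' @param production Regional production totals.
#' @param params A [model_params()] object.
#' @param prop A [proposal()].
#' @param weights Effective-subsidy multipliers (default unit).
#' @param quantile_threshold Managed/open-access split quantile (default 0.5).
#' @param removal_fraction Scalar in \[0, 1\] scaling every subsidy removal.
#' @return List of class `scenario_run`: `vessels` (fully annotated),
#'   `fleets`, `bau`, `reform` (trajectories), `result`
#'   (a [compare_scenarios()] table), `cap` (per-country cap summary or
#'   NULL), `proposal_name`.
#' @export
#' @examples
#' fx <- worked_example_fixture()
#' params <- model_params(phi = 0.188, K = 5e5, b0 = 2.5e5, MSY = 2e4,
#'                        epsilon = -1.2, p0 = 1500, beta = 1.3,
#'                        eta = 0.2, omega = 0.005)
#' run <- run_scenario_allocated(fx$vessels, params, fx$proposal)
#' run$result
run_scenario <- function(vessels, subsidies, production, params, prop,
                         weights = NULL, quantile_threshold = 0.5,
                         removal_fraction = 1) {
  rates <- compute_allocation_rates(vessels, subsidies, production)
  vessels <- allocate_vessel_economics(vessels, rates)
  run_scenario_allocated(vessels, params, prop, weights = weights,
                         subsidies = subsidies,
                         quantile_threshold = quantile_threshold,
                         removal_fraction = removal_fraction)
}

#' @rdname run_scenario
#' @export
run_scenario_allocated <- function(vessels, params, prop, weights = NULL,
                                   subsidies = NULL,
                                   quantile_threshold = 0.5,
                                   removal_fraction = 1) {
  vessels <- assign_management_tier(vessels, quantile_threshold)
  pol <- apply_proposal(vessels, prop, weights = weights,
                        subsidies = subsidies,
                        removal_fraction = removal_fraction)
  vessels <- partition_fleets(pol$vessels)
  fleets <- calibrate_fleets(vessels, params, weights)
  bau <- run_projection(fleets, params, "bau")
  reform <- run_projection(fleets, params, "reform")
  result <- compare_scenarios(bau, reform)
  structure(list(vessels = vessels, fleets = fleets, bau = bau,
                 reform = reform, result = result, cap = pol$cap,
                 proposal_name = prop$name),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run '%s'>\nFleet sizes: %s\n", x$proposal_name,
              paste(sprintf("%s=%d", x$fleets$fleet, x$fleets$n_vessels),
                    collapse = " ")))
  print(x$result)
  invisible(x)
}

#' The shipped default study fixture
#'
#' One fixed synthetic world -- the default [synthetic_config()] -- paired
#' with a default reform: prohibiting subsidies to fishing on overfished
#' stocks (B/B_MSY < 1) with all capacity-enhancing types removed, under the
#' shipped illustrative model parameters. This is the configuration the
#' qualitative-dynamics checks (effort decline in affected fleets, rebound in
#' unaffected fleets, monotonicity in removal fraction) run against.
#'
#' @param seed Seed for the synthetic world (default the configuration's own).
#' @return List: `inputs` (vessels, subsidies, production), `params`,
#'   `proposal`.
#' @export
default_scenario <- function(seed = NULL) {
  cfg <- synthetic_config()
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  inputs <- generate_inputs(cfg)
  params <- default_model_params()
  prop <- proposal(
    name = "Overfished stocks (B/B_MSY < 1)",
    disciplines = list(discipline("overfished", "stock_status_below",
                                  threshold = 1)))
  list(inputs = inputs, params = params, proposal = prop, config = cfg)
}

#' Shipped illustrative model parameters
#'
#' The default biological and economic parameters used with the synthetic
#' world. They are illustrative -- sized so that the synthetic fleet's
#' base-year harvest is close to the sustainable yield at the base biomass --
#' not estimates for any real fishery; the methods vignette records the
#' reasoning.
#'
#' @return A [model_params()] object.
#' @export
default_model_params <- function() {
  model_params(phi = 0.188, K = 5e7, b0 = 2.5e7, MSY = 2e6,
               epsilon = -1.2, p0 = 1500, beta = 1.3,
               eta = 0.2, omega = 0.005,
               base_year = 2018L, horizon_year = 2050L)
}
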