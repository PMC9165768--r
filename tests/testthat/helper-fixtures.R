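# Shared fixtures: a small synthetic configuration, toy model parameters and
# a hand-calibrated two-fleet table used by the projection tests.

tiny_cfg <- function(...) {
  args <- modifyList(list(n_vessels = 30L, n_flag_states = 3L,
                          n_fao_regions = 3L, seed = 7L),
                     list(...))
  do.call(synthetic_config, args)
}

toy_params <- function(...) {
  defaults <- list(phi = 0.2, K = 1e4, b0 = 4000, g = 0.3, epsilon = -1.5,
                   p0 = 10, beta = 1.2, eta = 0.05, omega = 0.001,
                   base_year = 2020L, horizon_year = 2023L)
  do.call(model_params, modifyList(defaults, list(...)))
}

# Two fleets (one managed-unaffected, one open-access-affected), calibrated
# with the package's scalar calibration operations so the base-year
# identities hold by construction.
toy_fleet_table <- function(params,
                            e0 = c(1000, 2000), h0 = c(300, 500),
                            s0 = c(0.2, 0.5), s_reformed = c(0.2, 0.1)) {
  data.frame(fleet = c("M-U", "OA-A"), managed = c(TRUE, FALSE),
             affected = c(FALSE, TRUE), n_vessels = c(1L, 1L),
             h0 = h0, e0 = e0, revenue0 = params$p0 * h0,
             subsidy_eff0_usd = s0 * e0,
             removed_eff_usd = (s0 - s_reformed) * e0,
             s0 = s0, s_reformed = s_reformed, inert = FALSE,
             q = calibrate_catchability(h0, params$b0, e0),
             alpha = calibrate_cost_coefficient(params$p0, h0, s0, e0,
                                                params$beta),
             stringsAsFactors = FALSE)
}

# A proposal whose predicate can never fire (stock status is always > 0).
null_proposal <- function() {
  proposal("No-op",
           list(discipline("overfished", "stock_status_below",
                           threshold = 1e-12)))
}
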