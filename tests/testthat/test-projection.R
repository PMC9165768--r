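test_that("model-parameter validation enforces the biological constraints", {
  expect_error(toy_params(epsilon = 0.5), "epsilon")
  expect_error(toy_params(b0 = 2e4), "b0")
  expect_error(toy_params(beta = 0.5), "beta")
  expect_error(toy_params(omega = 0.1), "eta > omega")
  p <- toy_params()
  expect_equal(growth_rate_from_msy(p$MSY, p$K, p$phi), p$g)
  # inconsistent MSY/g pair is refused
  expect_error(model_params(phi = 1, K = 1000, b0 = 500, MSY = 100, g = 0.5,
                            epsilon = -1, p0 = 10, beta = 1, eta = 1,
                            omega = 0),
               "inconsistent")
})

test_that("the biomass step has the textbook fixed points", {
  p <- toy_params()
  # no growth at carrying capacity
  expect_equal(surplus_production_step(p$K, p, 0), p$K)
  # extinction is absorbing
  expect_equal(surplus_production_step(0, p, 0), 0)
  # harvesting MSY at the most productive biomass is an equilibrium
  bmsy <- p$K * (p$phi + 1)^(-1 / p$phi)
  expect_equal(surplus_production_step(bmsy, p, p$MSY), bmsy,
               tolerance = 1e-9)
  # overharvest floors at zero
  expect_equal(surplus_production_step(100, p, 1e9), 0)
})

test_that("harvest, price, cost, profit and effort follow their equations", {
  expect_equal(fleet_harvest(1e-8, 1e4, 1e6), 100)
  expect_equal(fleet_harvest(1e-8, 1e4, 0), 0)
  expect_equal(total_harvest(c(1, 2, 3)), 6)

  p1 <- toy_params(epsilon = -1, p0 = 10,
                   delta = calibrate_demand_constant(100, 10, -1))
  expect_equal(price_from_harvest(100, p1), 10)
  expect_equal(price_from_harvest(200, p1), 5)
  p2 <- toy_params(epsilon = -2, p0 = 10,
                   delta = calibrate_demand_constant(100, 10, -2))
  expect_equal(price_from_harvest(400, p2), 5)
  expect_warning(price_from_harvest(1e-12, p1), "floor")

  expect_equal(fleet_cost(2, 10, 2), 200)
  expect_equal(fleet_cost(2, 0, 2), 0)
  expect_equal(fleet_profit(2, 50, 80, 0.01, 1000), 30)

  expect_equal(update_effort(10000, -1000, 2), 8000)
  expect_equal(update_effort(500, 0, 5), 500)
  expect_equal(update_effort(100, -1e6, 1), 0)  # floored
})

test_that("managed fleets respond more slowly than open-access fleets", {
  p <- toy_params()
  for (pi in c(-5000, -1, 1, 5000)) {
    d_oa <- abs(update_effort(1e6, pi, p$eta) - 1e6)
    d_m <- abs(update_effort(1e6, pi, p$omega) - 1e6)
    expect_lte(d_m, d_oa)
  }
})

test_that("a null reform reproduces BAU exactly", {
  params <- toy_params()
  fleets <- toy_fleet_table(params, s_reformed = c(0.2, 0.5))  # nothing removed
  bau <- run_projection(fleets, params, "bau")
  reform <- run_projection(fleets, params, "reform")
  expect_identical(bau$global, reform$global)
  expect_identical(bau$fleet, reform$fleet)
})

test_that("removing subsidies turns base-year profit negative and effort follows", {
  params <- toy_params()
  fleets <- toy_fleet_table(params)  # OA-A loses 0.4 USD/kWh
  reform <- run_projection(fleets, params, "reform")
  f <- reform$fleet
  oaa0 <- f[f$fleet == "OA-A" & f$year == params$base_year, ]
  # profit drops by exactly the removed subsidy revenue in the base year
  expect_equal(oaa0$profit, -(0.5 - 0.1) * 2000)
  oaa1 <- f[f$fleet == "OA-A" & f$year == params$base_year + 1, ]
  expect_equal(oaa1$effort, 2000 + params$eta * oaa0$profit)
  # the unaffected fleet is untouched in the first step
  mu <- f[f$fleet == "M-U", ]
  expect_equal(mu$effort[2], mu$effort[1])
})

test_that("the projection matches an independent step-by-step recurrence", {
  params <- toy_params()
  fleets <- toy_fleet_table(params)
  for (scen in c("bau", "reform")) {
    traj <- run_projection(fleets, params, scen)
    # independent recurrence, coded directly from the model definitions
    phi <- 0.2; g <- 0.3; K <- 1e4; b0 <- 4000; eps <- -1.5; p0 <- 10
    beta <- 1.2; eta <- 0.05; omega <- 0.001
    q <- c(300, 500) / (b0 * c(1000, 2000))
    alpha <- (p0 * c(300, 500) + c(0.2, 0.5) * c(1000, 2000)) /
      c(1000, 2000)^beta
    s <- if (scen == "reform") c(0.2, 0.1) else c(0.2, 0.5)
    speed <- c(omega, eta)
    h0tot <- 800
    b <- b0; e <- c(1000, 2000)
    for (i in 1:4) {  # 2020..2023
      h <- q * b * e
      grow <- ((phi + 1) / phi) * g * b * (1 - (b / K)^phi)
      if (sum(h) > b + grow) h <- h * (b + grow) / sum(h)
      price <- p0 * (sum(h) / h0tot)^(1 / eps)
      cost <- alpha * e^beta
      prof <- price * h - cost + s * e
      expect_equal(traj$global$biomass[i], b, tolerance = 1e-9)
      expect_equal(traj$global$price[i], price, tolerance = 1e-9)
      expect_equal(traj$global$harvest[i], sum(h), tolerance = 1e-9)
      expect_equal(traj$global$fishing_mortality[i], sum(h) / b,
                   tolerance = 1e-9)
      expect_equal(traj$fleet$effort[traj$fleet$year == 2019 + i], e,
                   tolerance = 1e-9)
      expect_equal(traj$fleet$profit[traj$fleet$year == 2019 + i], prof,
                   tolerance = 1e-9)
      b <- max(0, b + grow - sum(h))
      e <- pmax(0, speed * prof + e)
    }
  }
})

test_that("a self-replacing base year is a BAU fixed point", {
  # logistic curve (phi = 1), b0 at the most productive biomass, fleets
  # harvesting exactly the surplus: nothing moves
  params <- model_params(phi = 1, K = 1e4, b0 = 5000, g = 0.4, epsilon = -1.2,
                         p0 = 100, beta = 1.3, eta = 0.05, omega = 0.001,
                         base_year = 2018L, horizon_year = 2050L)
  grow <- surplus_production(5000, params)  # equals MSY = 1000
  fleets <- toy_fleet_table(params, e0 = c(1000, 3000),
                            h0 = c(0.25, 0.75) * grow,
                            s0 = c(0.3, 0.8), s_reformed = c(0.3, 0.8))
  traj <- run_projection(fleets, params, "bau")
  expect_equal(max(abs(traj$global$biomass - 5000)), 0, tolerance = 1e-6)
  expect_equal(max(abs(traj$global$harvest - grow)), 0, tolerance = 1e-6)
  expect_equal(max(abs(traj$global$profit)), 0, tolerance = 1e-5)
  eff <- traj$fleet$effort
  expect_equal(max(abs(eff - rep(c(1000, 3000), each = 33))), 0,
               tolerance = 1e-6)
})

test_that("biomass and effort stay non-negative for randomized parameters", {
  withr::with_seed(23L, {
    for (i in 1:15) {
      params <- model_params(
        phi = runif(1, 0.1, 2), K = 1e4, b0 = runif(1, 0.2, 1) * 1e4,
        MSY = runif(1, 100, 2000), epsilon = -runif(1, 0.5, 2),
        p0 = runif(1, 10, 200), beta = runif(1, 1, 1.6),
        eta = runif(1, 0.001, 0.1), omega = 1e-4,
        base_year = 2018L, horizon_year = 2040L)
      e0 <- runif(2, 500, 5000)
      h0 <- runif(2, 50, 500)
      s0 <- runif(2, 0, 2)
      fleets <- toy_fleet_table(params, e0 = e0, h0 = h0, s0 = s0,
                                s_reformed = s0 * runif(2, 0, 1))
      for (scen in c("bau", "reform")) {
        traj <- suppressWarnings(run_projection(fleets, params, scen))
        expect_true(all(traj$global$biomass >= 0))
        expect_true(all(traj$fleet$effort >= 0))
        expect_true(all(is.finite(traj$global$harvest)))
      }
    }
  })
})

test_that("scenario comparison reports percent changes at the horizon", {
  params <- toy_params()
  fleets <- toy_fleet_table(params, s_reformed = c(0.2, 0.5))
  bau <- run_projection(fleets, params, "bau")
  # identical trajectories -> all changes zero
  res <- compare_scenarios(bau, bau)
  expect_equal(res$pct_change, rep(0, 4))
  # a hand-modified horizon: +10% biomass
  reform <- bau
  reform$global$biomass[nrow(reform$global)] <-
    1.1 * bau$global$biomass[nrow(bau$global)]
  res <- compare_scenarios(bau, reform)
  expect_equal(res$pct_change[res$metric == "biomass"], 10)
  # zero BAU metric is flagged, not divided by
  bau0 <- bau
  bau0$global$revenue[nrow(bau0$global)] <- 0
  expect_warning(res <- compare_scenarios(bau0, reform), "revenue")
  expect_true(is.na(res$pct_change[res$metric == "revenue"]))
})

test_that("trajectories export as tidy CSV", {
  params <- toy_params()
  traj <- run_projection(toy_fleet_table(params), params, "reform")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  tab <- read.csv(path)
  expect_setequal(unique(tab$fleet), c("global", "M-U", "OA-A"))
  expect_true(all(c("year", "variable", "value", "scenario") %in% names(tab)))
  got <- tab$value[tab$fleet == "global" & tab$variable == "biomass"]
  expect_equal(got, traj$global$biomass)
})
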