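policy_vessels <- function() {
  fx <- worked_example_fixture()
  assign_management_tier(fx$vessels)
}

test_that("discipline predicates follow the negotiated threshold conventions", {
  v <- policy_vessels()
  # IUU listing
  d <- discipline("IUU", "iuu_listed")
  expect_equal(evaluate_discipline(v, d), v$iuu_listed)
  # overfished: strict 'below'
  v$stock_status <- rep(0.9, nrow(v))
  expect_true(all(evaluate_discipline(
    v, discipline("overfished", "stock_status_below", threshold = 1))))
  expect_false(any(evaluate_discipline(
    v, discipline("overfished", "stock_status_below", threshold = 0.8))))
  expect_false(any(evaluate_discipline(
    v, discipline("overfished", "stock_status_below", threshold = 0.9))))
  # high seas: 'at least' is >=
  v$high_seas_fraction <- c(0.96, 0.94, 0.95, rep(0, nrow(v) - 3))
  hit <- evaluate_discipline(
    v, discipline("OFOC", "high_seas_fraction_at_least", threshold = 0.95))
  expect_equal(hit[1:3], c(TRUE, FALSE, TRUE))
})

test_that("development-status exemptions override every predicate", {
  v <- policy_vessels()
  v$development_status <- rep(c("developed", "LDC"), 5)
  d <- discipline("IUU", "iuu_listed", exempt_development = "LDC")
  hit <- evaluate_discipline(v, d)
  expect_false(any(hit[v$development_status == "LDC"]))
  expect_equal(hit[v$development_status == "developed"],
               v$iuu_listed[v$development_status == "developed"])
  # exemption holds even for an always-triggering predicate
  d2 <- discipline("OFOC", "always", exempt_development = c("LDC", "developing"))
  expect_equal(evaluate_discipline(v, d2), v$development_status == "developed")
})

test_that("affected-vessel selection unions scopes and partitions exhaustively", {
  v <- policy_vessels()
  # nothing triggers
  sel <- select_affected_vessels(v, null_proposal())
  expect_false(any(sel$vessels$affected))
  # the worked example: 3 of 10 vessels affected
  fx <- worked_example_fixture()
  sel <- select_affected_vessels(v, fx$proposal)
  expect_equal(sum(sel$vessels$affected), 3L)
  # overlapping disciplines: affected once, scope is the union
  prop <- proposal("both", list(
    discipline("IUU", "iuu_listed"),
    discipline("OFOC", "high_seas_fraction_at_least", threshold = 0,
               removal_scope = "listed_types", listed_types = "management")))
  sel <- select_affected_vessels(v, prop)
  expect_true(all(sel$vessels$affected))
  sc <- sel$scopes[[which(v$iuu_listed)[1]]]
  expect_true(sc$all_capacity_enhancing)
  expect_equal(sc$listed_types, "management")
})

test_that("adding a discipline never shrinks the affected set", {
  cfg <- synthetic_config(n_vessels = 150L, seed = 31L)
  v <- generate_vessel_database(cfg)
  pool <- list(discipline("IUU", "iuu_listed"),
               discipline("overfished", "stock_status_below", threshold = 1),
               discipline("OFOC", "high_seas_fraction_at_least",
                          threshold = 0.95),
               discipline("OFOC", "distant_water_fraction_at_least",
                          threshold = 0.5, removal_scope = "listed_types",
                          listed_types = "fuel"))
  prev <- rep(FALSE, nrow(v))
  for (k in seq_along(pool)) {
    sel <- select_affected_vessels(v, proposal("grow", pool[seq_len(k)]))
    expect_true(all(prev <= sel$vessels$affected))
    prev <- sel$vessels$affected
  }
})

test_that("removal amounts respect scope and never exceed holdings", {
  subs <- c(fuel = 60, management = 40)
  all_ce <- list(all_capacity_enhancing = TRUE, listed_types = character(0))
  # only capacity-enhancing types go under the general scope
  expect_equal(compute_removal_amounts(subs, all_ce), 60)
  # a vessel with only non-capacity-enhancing subsidies loses nothing
  expect_equal(compute_removal_amounts(c(management = 40), all_ce), 0)
  # listed types are removed regardless of the capacity-enhancing flag
  listed <- list(all_capacity_enhancing = FALSE, listed_types = "management")
  expect_equal(compute_removal_amounts(subs, listed), 40)
  # union scope removes each dollar once
  both <- list(all_capacity_enhancing = TRUE, listed_types = "fuel")
  expect_equal(compute_removal_amounts(subs, both), 60)
  # weighting applies to the removed dollars
  expect_equal(compute_removal_amounts(subs, listed,
                                       weights = c(fuel = 1, management = 0.5)),
               20)
  # property: removal <= effective holdings, random draws
  withr::with_seed(9L, {
    types <- names(capacity_enhancing_types())
    for (i in 1:25) {
      s <- setNames(runif(length(types), 0, 100), types)
      w <- setNames(runif(length(types), 0, 2), types)
      sc <- list(all_capacity_enhancing = runif(1) < 0.5,
                 listed_types = sample(types, sample(0:3, 1)))
      removed <- compute_removal_amounts(s, sc, w)
      expect_gte(removed, 0)
      expect_lte(removed, apply_effective_subsidy_weights(s, w) + 1e-12)
    }
  })
})

cap_profiles <- function(amounts, status = "developed", landed = 2e8,
                         types = c("fuel", "management"),
                         ce = c(TRUE, FALSE)) {
  data.frame(flag_state = "AAA", subsidy_type = types, amount_usd = amounts,
             capacity_enhancing = ce, development_status = status,
             landed_value_usd = landed, capture_production_t = 1e5,
             total_subsidies_usd = sum(amounts), stringsAsFactors = FALSE)
}

test_that("cap rules remove the excess over the tier cap", {
  rule <- cap_rule(tier_by_status = c(developed = "t1", developing = "t2",
                                      LDC = "t2"),
                   cap_basis = "percent_of_current_subsidies",
                   cap_percent_by_tier = c(t1 = 3, t2 = 5))
  # $10M at a 3% cap -> $9.7M removed
  out <- apply_cap_rule(cap_profiles(c(6e6, 4e6), ce = c(TRUE, TRUE)), rule)
  expect_equal(out$removed_usd, 9.7e6)
  # landed-value basis: cap above current subsidies -> nothing removed
  rule_lv <- cap_rule(tier_by_status = c(developed = "t1", developing = "t1",
                                         LDC = "t1"),
                      cap_basis = "percent_of_landed_value",
                      cap_percent_by_tier = c(t1 = 5))
  out <- apply_cap_rule(cap_profiles(c(5e6, 3e6), landed = 2e8,
                                     ce = c(TRUE, TRUE)), rule_lv)
  expect_equal(out$removed_usd, 0)  # cap $10M > $8M held
  # all types green-box: empty cap base, nothing to remove
  rule_gb <- cap_rule(tier_by_status = c(developed = "t1", developing = "t1",
                                         LDC = "t1"),
                      cap_basis = "percent_of_current_subsidies",
                      cap_percent_by_tier = c(t1 = 3),
                      green_box_types = c("fuel", "management"))
  out <- apply_cap_rule(cap_profiles(c(6e6, 4e6)), rule_gb)
  expect_equal(out$removed_usd, 0)
  # unmapped development status is a configuration error
  expect_error(cap_rule(tier_by_status = c(developed = "t1"),
                        cap_percent_by_tier = c(t1 = 3)),
               "every development status")
  # a 100% cap of current subsidies removes exactly nothing
  rule_100 <- cap_rule(tier_by_status = c(developed = "t1", developing = "t1",
                                          LDC = "t1"),
                       cap_basis = "percent_of_current_subsidies",
                       cap_percent_by_tier = c(t1 = 100))
  withr::with_seed(13L, {
    for (i in 1:10) {
      prof <- cap_profiles(runif(2, 0, 1e7),
                           status = sample(c("developed", "developing", "LDC"), 1))
      expect_equal(apply_cap_rule(prof, rule_100)$removed_usd, 0)
    }
  })
})

test_that("apply_proposal computes removals once across mechanisms", {
  fx <- worked_example_fixture()
  v <- assign_management_tier(fx$vessels)
  out <- apply_proposal(v, fx$proposal)
  expect_equal(sum(out$vessels$affected), 3L)
  # affected vessels lose all fuel (CE) but keep management subsidies
  aff <- out$vessels$affected
  expect_equal(out$vessels$removed_nominal_usd[aff], rep(600000, 3))
  expect_equal(out$vessels$removed_nominal_usd[!aff], rep(0, 7))
  # removal never exceeds effective holdings
  expect_true(all(out$vessels$removed_effective_usd <=
                    out$vessels$effective_subsidy_usd + 1e-9))
  # a duplicate discipline changes nothing (idempotent union)
  twice <- proposal("twice", c(fx$proposal$disciplines,
                               fx$proposal$disciplines))
  out2 <- apply_proposal(v, twice)
  expect_equal(out2$vessels$removed_effective_usd,
               out$vessels$removed_effective_usd)
  # removal_fraction scales linearly
  half <- apply_proposal(v, fx$proposal, removal_fraction = 0.5)
  expect_equal(half$vessels$removed_nominal_usd,
               out$vessels$removed_nominal_usd / 2)
})

test_that("cap rules inside a proposal draw down vessels proportionally", {
  fx <- worked_example_fixture()
  v <- assign_management_tier(fx$vessels)
  subsidies <- data.frame(flag_state = "FS01",
                          subsidy_type = c("fuel", "management"),
                          amount_usd = c(sum(v$subsidy_usd__fuel),
                                         sum(v$subsidy_usd__management)),
                          capacity_enhancing = c(TRUE, FALSE),
                          stringsAsFactors = FALSE)
  rule <- cap_rule(tier_by_status = c(developed = "t1", developing = "t1",
                                      LDC = "t1"),
                   cap_basis = "percent_of_current_subsidies",
                   cap_percent_by_tier = c(t1 = 10),
                   green_box_types = "management")
  prop <- proposal("cap only", cap_rules = rule)
  out <- apply_proposal(v, prop, subsidies = subsidies)
  # 90% of the fuel (non-green-box) base is removed, pro rata per vessel
  expect_equal(out$cap$removed_usd, 0.9 * sum(v$subsidy_usd__fuel))
  expect_equal(out$vessels$removed_nominal_usd, 0.9 * v$subsidy_usd__fuel)
  expect_true(all(out$vessels$affected))
})
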