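# Subsidy-reform disciplines, proposals and cap-and-tier rules.
#
# A discipline is a predicate over vessel behaviour plus a removal scope; a
# proposal is a set of disciplines, optionally with a country-level cap rule.
# Threshold conventions follow the negotiating language: "at least X%" is >=,
# "overfished, below B/B_MSY Y" is strict <. Removal scopes union across
# triggering disciplines and dollars are never removed twice: the per-type
# removal fraction is the maximum over mechanisms.

DISCIPLINE_CATEGORIES <- c("IUU", "overfished", "OFOC")
DISCIPLINE_PREDICATES <- c("iuu_listed", "stock_status_below",
                           "high_seas_fraction_at_least",
                           "distant_water_fraction_at_least",
                           "disputed_area", "development_status_in",
                           "always")
REMOVAL_SCOPES <- c("all_capacity_enhancing", "listed_types")

#' Define a subsidy-reform discipline
#'
#' A discipline prohibits subsidies to vessels satisfying a predicate. The
#' available predicates mirror the vocabulary of the WTO negotiations:
#' appearance on an IUU list, fishing where stocks are overfished
#' (`stock_status_below`, strict `<` on a B/B_MSY-like score), spending at
#' least a threshold fraction of time on the high seas or in distant waters
#' (`>=`), fishing disputed areas, flag development status, or `always`
#' (every vessel -- the "ambitious reform" selector that removes a subsidy
#' class outright). Vessels whose flag development status is in
#' `exempt_development` (special and differential treatment) never trigger
#' the discipline.
#'
#' @param category One of `"IUU"`, `"overfished"`, `"OFOC"`.
#' @param predicate One of the predicate names above.
#' @param threshold Numeric parameter for the threshold predicates
#'   (`stock_status_below` in B/B_MSY units; the fraction predicates as a
#'   proportion in \[0, 1\]).
#' @param statuses Development statuses for `development_status_in`.
#' @param removal_scope `"all_capacity_enhancing"` (IUU/overfished
#'   disciplines) or `"listed_types"` (overcapacity disciplines naming
#'   specific types).
#' @param listed_types Non-empty character vector of subsidy types when
#'   `removal_scope = "listed_types"`; the listed types are removed
#'   regardless of their capacity-enhancing flag.
#' @param exempt_development Development statuses exempt from the discipline.
#' @return An object of class `discipline`.
#' @export
#' @examples
#' discipline("overfished", "stock_status_below", threshold = 1)
discipline <- function(category, predicate, threshold = NULL, statuses = NULL,
                       removal_scope = "all_capacity_enhancing",
                       listed_types = NULL,
                       exempt_development = character(0)) {
  if (length(category) != 1L || !category %in% DISCIPLINE_CATEGORIES)
    stop("unknown discipline category '", category, "'; expected one of: ",
         paste(DISCIPLINE_CATEGORIES, collapse = ", "))
  if (length(predicate) != 1L || !predicate %in% DISCIPLINE_PREDICATES)
    stop("unknown discipline predicate '", predicate, "'; expected one of: ",
         paste(DISCIPLINE_PREDICATES, collapse = ", "))
  if (length(removal_scope) != 1L || !removal_scope %in% REMOVAL_SCOPES)
    stop("unknown removal_scope '", removal_scope, "'; expected one of: ",
         paste(REMOVAL_SCOPES, collapse = ", "))
  if (predicate %in% c("high_seas_fraction_at_least",
                       "distant_water_fraction_at_least")) {
    if (is.null(threshold) || threshold < 0 || threshold > 1)
      stop("predicate ", predicate, " needs a threshold in [0, 1]")
  }
  if (predicate == "stock_status_below") {
    if (is.null(threshold) || threshold <= 0)
      stop("predicate stock_status_below needs a positive B/B_MSY threshold")
  }
  if (predicate == "development_status_in") {
    if (is.null(statuses) || !all(statuses %in% DEVELOPMENT_STATUSES))
      stop("predicate development_status_in needs statuses among: ",
           paste(DEVELOPMENT_STATUSES, collapse = ", "))
  }
  if (removal_scope == "listed_types") {
    if (is.null(listed_types) || length(listed_types) == 0L)
      stop("removal_scope 'listed_types' needs a non-empty listed_types")
  } else {
    listed_types <- character(0)
  }
  if (!all(exempt_development %in% DEVELOPMENT_STATUSES))
    stop("exempt_development must be development statuses")
  structure(list(category = category, predicate = predicate,
                 threshold = threshold, statuses = statuses,
                 removal_scope = removal_scope,
                 listed_types = as.character(listed_types),
                 exempt_development = as.character(exempt_development)),
            class = "discipline")
}

#' @export
print.discipline <- function(x, ...) {
  thr <- if (!is.null(x$threshold)) paste0(" @ ", x$threshold) else ""
  cat(sprintf("<discipline %s: %s%s -> %s>\n", x$category, x$predicate, thr,
              x$removal_scope))
  invisible(x)
}

#' Define a cap-and-tier rule
#'
#' Countries are tiered by development status and each tier's permissible
#' subsidies are capped at a percentage of a basis: either current
#' (non-green-box) subsidy levels or landed value. Green-box types are exempt
#' from the cap base. Anything above the cap is removed, spread across the
#' country's vessels proportionally to their subsidy allocations.
#'
#' @param tier_by_status Named character mapping every development status to
#'   a tier name.
#' @param cap_basis `"percent_of_current_subsidies"` or
#'   `"percent_of_landed_value"`.
#' @param cap_percent_by_tier Named numeric, percentage cap per tier
#'   (e.g. `c(tier1 = 3, tier2 = 5)` for a 3%/5% cap).
#' @param green_box_types Subsidy types exempt from the cap base.
#' @return An object of class `cap_rule`.
#' @export
cap_rule <- function(tier_by_status,
                     cap_basis = c("percent_of_current_subsidies",
                                   "percent_of_landed_value"),
                     cap_percent_by_tier,
                     green_box_types = character(0)) {
  cap_basis <- match.arg(cap_basis)
  if (!all(DEVELOPMENT_STATUSES %in% names(tier_by_status)))
    stop("tier_by_status must map every development status (",
         paste(DEVELOPMENT_STATUSES, collapse = ", "), ") to a tier")
  if (any(cap_percent_by_tier < 0))
    stop("cap_percent_by_tier percentages must be >= 0")
  missing <- setdiff(unique(unname(tier_by_status)), names(cap_percent_by_tier))
  if (length(missing) > 0L)
    stop("no cap percentage for tier(s): ", paste(missing, collapse = ", "))
  structure(list(tier_by_status = tier_by_status, cap_basis = cap_basis,
                 cap_percent_by_tier = cap_percent_by_tier,
                 green_box_types = as.character(green_box_types)),
            class = "cap_rule")
}

#' Define a reform proposal
#'
#' A proposal (reform package) is a named set of disciplines, optionally with
#' a cap-and-tier rule; it must contain at least one of the two.
#'
#' @param name Proposal name.
#' @param disciplines List of [discipline()] objects.
#' @param cap_rules Optional [cap_rule()].
#' @return An object of class `proposal`.
#' @export
proposal <- function(name, disciplines = list(), cap_rules = NULL) {
  if (!all(vapply(disciplines, inherits, logical(1), "discipline")))
    stop("disciplines must be a list of discipline objects")
  if (length(disciplines) == 0L && is.null(cap_rules))
    stop("a proposal needs at least one discipline or a cap rule")
  if (!is.null(cap_rules) && !inherits(cap_rules, "cap_rule"))
    stop("cap_rules must be a cap_rule object")
  structure(list(name = name, disciplines = disciplines,
                 cap_rules = cap_rules),
            class = "proposal")
}

#' @export
print.proposal <- function(x, ...) {
  cat(sprintf("<proposal '%s': %d discipline(s)%s>\n", x$name,
              length(x$disciplines),
              if (!is.null(x$cap_rules)) " + cap rule" else ""))
  invisible(x)
}

#' Which vessels does a discipline affect?
#'
#' Evaluates the discipline's predicate for every vessel; a vessel whose flag
#' development status is exempted never triggers, regardless of predicate.
#'
#' @param vessels A vessel database.
#' @param d A [discipline()].
#' @return Logical vector, one entry per vessel.
#' @export
evaluate_discipline <- function(vessels, d) {
  stopifnot(inherits(d, "discipline"))
  hit <- switch(d$predicate,
    iuu_listed = vessels$iuu_listed,
    stock_status_below = vessels$stock_status < d$threshold,
    high_seas_fraction_at_least = vessels$high_seas_fraction >= d$threshold,
    distant_water_fraction_at_least =
      vessels$distant_water_fraction >= d$threshold,
    disputed_area = vessels$disputed_area,
    development_status_in = vessels$development_status %in% d$statuses,
    always = rep(TRUE, nrow(vessels)))
  hit & !(vessels$development_status %in% d$exempt_development)
}

#' Partition vessels into affected and unaffected under a proposal
#'
#' A vessel is affected when at least one discipline triggers; its removal
#' scope is the union of the triggering disciplines' scopes. The partition is
#' exhaustive and disjoint. (Country cap rules act on subsidy magnitudes, not
#' on this predicate partition; see [apply_proposal()].)
#'
#' @param vessels A vessel database.
#' @param prop A [proposal()].
#' @return List with `vessels` (input plus logical `affected` column),
#'   `triggers` (vessel x discipline logical matrix), and `scopes` (per
#'   vessel: list with `all_capacity_enhancing` flag and `listed_types`).
#' @export
select_affected_vessels <- function(vessels, prop) {
  stopifnot(inherits(prop, "proposal"))
  nd <- length(prop$disciplines)
  triggers <- matrix(FALSE, nrow = nrow(vessels), ncol = nd)
  for (j in seq_len(nd))
    triggers[, j] <- evaluate_discipline(vessels, prop$disciplines[[j]])
  affected <- if (nd > 0) rowSums(triggers) > 0 else rep(FALSE, nrow(vessels))
  scopes <- lapply(seq_len(nrow(vessels)), function(i) {
    if (!affected[i])
      return(list(all_capacity_enhancing = FALSE, listed_types = character(0)))
    trig <- prop$disciplines[triggers[i, ]]
    list(all_capacity_enhancing =
           any(vapply(trig, function(d) d$removal_scope == "all_capacity_enhancing",
                      logical(1))),
         listed_types = unique(unlist(lapply(trig, function(d) d$listed_types))))
  })
  vessels$affected <- affected
  list(vessels = vessels, triggers = triggers, scopes = scopes)
}

#' Effective subsidies removed from one vessel
#'
#' Scope `all_capacity_enhancing` removes every type flagged
#' capacity-enhancing; scope `listed_types` removes exactly the listed types,
#' irrespective of their capacity-enhancing flag. When both apply the removed
#' type set is the union, so no dollar is removed twice. The returned value
#' is in effective USD (post multiplier weighting) and never exceeds the
#' vessel's effective holdings.
#'
#' @param subsidies_by_type Named numeric, nominal USD by subsidy type.
#' @param scope List with `all_capacity_enhancing` (logical) and
#'   `listed_types` (character), as produced by [select_affected_vessels()].
#' @param weights Named effective-subsidy multipliers (default unit).
#' @param ce_types Named logical classifying each type as capacity-enhancing
#'   (default [capacity_enhancing_types()]).
#' @return Effective USD removed.
#' @export
#' @examples
#' compute_removal_amounts(c(fuel = 60, management = 40),
#'                         list(all_capacity_enhancing = TRUE,
#'                              listed_types = character(0)))
compute_removal_amounts <- function(subsidies_by_type, scope,
                                    weights = NULL,
                                    ce_types = capacity_enhancing_types()) {
  if (length(subsidies_by_type) == 0L) return(0)
  types <- names(subsidies_by_type)
  if (is.null(weights)) weights <- default_effective_weights(types)
  removed <- character(0)
  if (isTRUE(scope$all_capacity_enhancing)) {
    unknown <- setdiff(types, names(ce_types))
    if (length(unknown) > 0L)
      stop("no capacity-enhancing classification for type(s): ",
           paste(unknown, collapse = ", "))
    removed <- types[ce_types[types]]
  }
  removed <- union(removed, intersect(scope$listed_types, types))
  if (length(removed) == 0L) return(0)
  apply_effective_subsidy_weights(subsidies_by_type[removed], weights)
}

#' Country-level profiles for cap-and-tier rules
#'
#' Aggregates a vessel database and subsidy table to the country level: one
#' row per (flag state, subsidy type) carrying the flag's development status,
#' landed value and capture production, plus optionally subsidy dollars per
#' fisher when fisher counts are supplied.
#'
#' @param vessels A vessel database with allocations filled.
#' @param subsidies A country subsidy table.
#' @param fishers_by_flag Optional named numeric of fisher counts per flag.
#' @return Data.frame of class `country_profiles`.
#' @export
country_profiles <- function(vessels, subsidies, fishers_by_flag = NULL) {
  validate_subsidy_table(subsidies)
  status <- tapply(vessels$development_status, vessels$flag_state,
                   function(x) x[1])
  landed <- tapply(vessels$revenue_usd, vessels$flag_state, sum)
  catch <- tapply(vessels$catch_t, vessels$flag_state, sum)
  prof <- subsidies
  prof$development_status <- unname(status[prof$flag_state])
  if (anyNA(prof$development_status))
    stop("subsidy table names flag state(s) absent from the vessel database: ",
         paste(unique(prof$flag_state[is.na(prof$development_status)]),
               collapse = ", "))
  prof$landed_value_usd <- unname(landed[prof$flag_state])
  prof$capture_production_t <- unname(catch[prof$flag_state])
  totals <- tapply(subsidies$amount_usd, subsidies$flag_state, sum)
  prof$total_subsidies_usd <- unname(totals[prof$flag_state])
  if (!is.null(fishers_by_flag)) {
    prof$subsidy_per_fisher_usd <-
      prof$total_subsidies_usd / unname(fishers_by_flag[prof$flag_state])
  }
  class(prof) <- c("country_profiles", "data.frame")
  prof
}

#' Subsidies removed from each country under a cap rule
#'
#' For each flag state: tier from development status, cap = tier percentage
#' of the basis (current non-green-box subsidies or landed value), and
#' removal = max(0, non-green-box subsidies - cap). The removal fraction
#' applies uniformly to the country's non-green-box subsidy dollars, which
#' spreads the drawdown over vessels proportionally to their allocations.
#'
#' @param profiles A [country_profiles()] data.frame.
#' @param rule A [cap_rule()].
#' @return Data.frame: `flag_state`, `tier`, `cap_usd`, `capped_base_usd`,
#'   `removed_usd`, `removal_fraction`.
#' @export
#' @examples
#' # a 3% cap on $10M of current subsidies removes $9.7M
apply_cap_rule <- function(profiles, rule) {
  stopifnot(inherits(rule, "cap_rule"))
  flags <- unique(profiles$flag_state)
  out <- lapply(flags, function(f) {
    rows <- profiles[profiles$flag_state == f, , drop = FALSE]
    status <- rows$development_status[1]
    tier <- rule$tier_by_status[[status]]
    if (is.null(tier) || is.na(tier))
      stop("cap rule maps no tier for development status '", status, "'")
    pct <- rule$cap_percent_by_tier[[tier]]
    if (is.null(pct) || is.na(pct))
      stop("cap rule has no percentage for tier '", tier, "'")
    base <- sum(rows$amount_usd[!(rows$subsidy_type %in% rule$green_box_types)])
    basis <- switch(rule$cap_basis,
                    percent_of_current_subsidies = base,
                    percent_of_landed_value = rows$landed_value_usd[1])
    cap <- pct / 100 * basis
    removed <- max(0, base - cap)
    data.frame(flag_state = f, tier = tier, cap_usd = cap,
               capped_base_usd = base, removed_usd = removed,
               removal_fraction = if (base > 0) removed / base else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Apply a full proposal to an allocated vessel database
#'
#' Runs the discipline predicates and any cap rule and computes, per vessel
#' and subsidy type, the fraction of nominal subsidies removed: 1 for types
#' in a triggering discipline's removal scope, the country's cap removal
#' fraction for non-green-box types under a cap, and the maximum where both
#' apply (dollars are never removed twice). `removal_fraction` scales all
#' removals, for exploring partial implementation.
#'
#' @param vessels A vessel database with allocations and (for cap rules) a
#'   subsidy table.
#' @param prop A [proposal()].
#' @param weights Named effective-subsidy multipliers (default unit).
#' @param subsidies Country subsidy table; required when the proposal has a
#'   cap rule.
#' @param removal_fraction Scalar in \[0, 1\] scaling every removal.
#' @return List: `vessels` (with `affected`, `effective_subsidy_usd`,
#'   `removed_nominal_usd`, `removed_effective_usd` columns), `fractions`
#'   (vessel x type removal-fraction matrix), `cap` (per-country cap summary
#'   or NULL).
#' @export
apply_proposal <- function(vessels, prop, weights = NULL, subsidies = NULL,
                           removal_fraction = 1) {
  stopifnot(inherits(prop, "proposal"))
  if (removal_fraction < 0 || removal_fraction > 1)
    stop("removal_fraction must lie in [0, 1]")
  sub_cols <- subsidy_columns(vessels)
  if (length(sub_cols) == 0L)
    stop("vessels carry no subsidy allocations; run allocate_vessel_economics first")
  types <- subsidy_col_type(sub_cols)
  if (is.null(weights)) weights <- default_effective_weights(types)
  missing_w <- setdiff(types, names(weights))
  if (length(missing_w) > 0L)
    stop("no effective-subsidy multiplier for type(s): ",
         paste(missing_w, collapse = ", "))
  amounts <- as.matrix(vessels[, sub_cols, drop = FALSE])
  colnames(amounts) <- types
  ce <- capacity_enhancing_types()

  sel <- select_affected_vessels(vessels, prop)
  frac <- matrix(0, nrow = nrow(vessels), ncol = length(types),
                 dimnames = list(NULL, types))
  for (i in which(sel$vessels$affected)) {
    sc <- sel$scopes[[i]]
    rm_types <- character(0)
    if (sc$all_capacity_enhancing) rm_types <- types[ce[types] %in% TRUE]
    rm_types <- union(rm_types, intersect(sc$listed_types, types))
    frac[i, rm_types] <- 1
  }

  cap_summary <- NULL
  cap_affected <- rep(FALSE, nrow(vessels))
  if (!is.null(prop$cap_rules)) {
    if (is.null(subsidies))
      stop("a proposal with a cap rule needs the country subsidy table")
    prof <- country_profiles(vessels, subsidies)
    cap_summary <- apply_cap_rule(prof, prop$cap_rules)
    gb <- prop$cap_rules$green_box_types
    capped_types <- setdiff(types, gb)
    f_by_flag <- setNames(cap_summary$removal_fraction, cap_summary$flag_state)
    vf <- f_by_flag[vessels$flag_state]
    vf[is.na(vf)] <- 0
    for (ty in capped_types) frac[, ty] <- pmax(frac[, ty], vf)
    cap_affected <- vf > 0 & rowSums(amounts[, capped_types, drop = FALSE]) > 0
  }

  affected <- sel$vessels$affected | cap_affected
  frac <- frac * removal_fraction
  w <- weights[types]
  vessels$effective_subsidy_usd <- as.numeric(amounts %*% w)
  vessels$removed_nominal_usd <- rowSums(frac * amounts)
  vessels$removed_effective_usd <- as.numeric((frac * amounts) %*% w)
  vessels$affected <- affected
  list(vessels = vessels, fractions = frac, cap = cap_summary)
}
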