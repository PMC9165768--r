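# Effort-weighted allocation of catches, landed value and subsidies.
#
# Rates are computed from country/region totals divided by observed fishing
# effort (kWh) and then multiplied back onto each vessel's effort, so
# flag-level sums of the allocations reproduce the totals by construction.
# Catch and revenue rates are per (flag state, FAO region); subsidy rates are
# per flag state only, with the country's subsidy-type mix preserved
# vessel-by-vessel.

#' Subsidy rate for one flag state
#'
#' A country providing `subsidy_total` USD to vessels that together expended
#' `effort_total` kWh has a subsidy rate of `subsidy_total / effort_total`
#' USD/kWh. For example, $2 million over 15 million kWh gives $0.133 USD/kWh.
#'
#' @param subsidy_total Total subsidies (USD, >= 0).
#' @param effort_total Total fishing effort (kWh, > 0).
#' @return Subsidy rate in USD/kWh.
#' @export
#' @examples
#' compute_flag_subsidy_rate(2e6, 15e6)
compute_flag_subsidy_rate <- function(subsidy_total, effort_total) {
  if (any(effort_total <= 0))
    stop("effort_total must be > 0 to form a subsidy rate")
  if (any(subsidy_total < 0)) stop("subsidy_total must be >= 0")
  subsidy_total / effort_total
}

#' Catch and revenue rates for one (flag state, FAO region)
#'
#' Dividing regional catch (tonnes) and landed value (USD) by the regional
#' fishing effort (kWh) of a flag's vessels gives the rates used to allocate
#' production to vessels: 0.5 million tonnes and $1 million over 5 million
#' kWh give 0.1 tonnes/kWh and $0.2 USD/kWh.
#'
#' @param catch Regional catch (tonnes, >= 0).
#' @param revenue Regional landed value (USD, >= 0).
#' @param effort Regional effort (kWh, > 0).
#' @return Named numeric: `catch_rate_t_per_kwh`, `revenue_rate_usd_per_kwh`.
#' @export
#' @examples
#' compute_region_rates(5e5, 1e6, 5e6)
compute_region_rates <- function(catch, revenue, effort) {
  if (any(effort <= 0)) stop("effort must be > 0 to form catch/revenue rates")
  if (any(catch < 0) || any(revenue < 0))
    stop("catch and revenue must be >= 0")
  c(catch_rate_t_per_kwh = catch / effort,
    revenue_rate_usd_per_kwh = revenue / effort)
}

#' Allocation rates from country and regional totals
#'
#' Builds the full rate set for a vessel database: one subsidy rate (USD/kWh)
#' per flag state, catch (tonnes/kWh) and revenue (USD/kWh) rates per
#' (flag state, FAO region), and each country's subsidy-type mix. Effort
#' denominators are the sums over the vessels of the database.
#'
#' @param vessels A vessel database.
#' @param subsidies A country subsidy table (see [validate_subsidy_table()]).
#' @param production Regional production totals with columns `flag_state`,
#'   `fao_region`, `catch_t`, `revenue_usd`.
#' @return An object of class `allocation_rates`: list with data.frames
#'   `subsidy` (per flag), `region` (per flag-region) and `type_shares`.
#' @export
compute_allocation_rates <- function(vessels, subsidies, production) {
  validate_vessels(vessels, allow_empty = FALSE)
  validate_subsidy_table(subsidies)
  tot <- vessel_total_effort(vessels)
  flag_effort <- tapply(tot, vessels$flag_state, sum)

  flag_totals <- tapply(subsidies$amount_usd, subsidies$flag_state, sum)
  flags <- names(flag_totals)
  no_eff <- flags[!(flags %in% names(flag_effort))] # subsidized, unobserved
  no_eff <- no_eff[flag_totals[no_eff] > 0]
  if (length(no_eff) > 0L)
    stop("no observed effort for subsidized flag state(s): ",
         paste(no_eff, collapse = ", "))
  flags <- intersect(flags, names(flag_effort))
  subsidy <- data.frame(
    flag_state = flags,
    subsidy_rate_usd_per_kwh = compute_flag_subsidy_rate(
      as.numeric(flag_totals[flags]), as.numeric(flag_effort[flags])),
    stringsAsFactors = FALSE)

  eff_long <- flag_region_effort(vessels)
  key <- paste(production$flag_state, production$fao_region, sep = "\r")
  ekey <- paste(eff_long$flag_state, eff_long$fao_region, sep = "\r")
  eff_match <- eff_long$effort_kwh[match(key, ekey)]
  bad <- is.na(eff_match) | eff_match <= 0
  bad <- bad & (production$catch_t > 0 | production$revenue_usd > 0)
  if (any(bad))
    stop("no observed effort for production in (flag, region): ",
         paste(paste(production$flag_state[bad], production$fao_region[bad],
                     sep = "/"), collapse = ", "))
  keep <- !is.na(eff_match) & eff_match > 0
  region <- data.frame(
    flag_state = production$flag_state[keep],
    fao_region = as.character(production$fao_region[keep]),
    catch_rate_t_per_kwh = production$catch_t[keep] / eff_match[keep],
    revenue_rate_usd_per_kwh = production$revenue_usd[keep] / eff_match[keep],
    stringsAsFactors = FALSE)

  type_shares <- subsidies[, c("flag_state", "subsidy_type", "amount_usd",
                               "capacity_enhancing")]
  out <- list(subsidy = subsidy, region = region, type_shares = type_shares,
              flag_effort = data.frame(flag_state = names(flag_effort),
                                       effort_kwh = as.numeric(flag_effort),
                                       stringsAsFactors = FALSE))
  class(out) <- "allocation_rates"
  out
}

#' @export
print.allocation_rates <- function(x, ...) {
  cat("Allocation rates:", nrow(x$subsidy), "flag states,",
      nrow(x$region), "flag-region cells\n")
  invisible(x)
}

#' Allocate catches, landed value and subsidies to vessels
#'
#' Fills `catch_t`, `revenue_usd` and one `subsidy_usd__<type>` column per
#' subsidy type. A vessel's catch and revenue are the sums over regions of
#' the (flag, region) rate times its regional effort; its subsidies are the
#' flag totals by type scaled by its share of the flag's total effort. Sums
#' over a flag's vessels therefore reproduce the country and regional totals.
#'
#' @param vessels A vessel database.
#' @param rates An [compute_allocation_rates()] result.
#' @return `vessels` with allocation columns filled.
#' @export
allocate_vessel_economics <- function(vessels, rates) {
  stopifnot(inherits(rates, "allocation_rates"))
  validate_vessels(vessels, allow_empty = FALSE)
  eff_cols <- effort_columns(vessels)
  regions <- effort_col_region(eff_cols)

  catch <- numeric(nrow(vessels))
  revenue <- numeric(nrow(vessels))
  rkey <- paste(rates$region$flag_state, rates$region$fao_region, sep = "\r")
  for (i in seq_along(eff_cols)) {
    e <- vessels[[eff_cols[i]]]
    has <- e > 0
    if (!any(has)) next
    idx <- match(paste(vessels$flag_state[has], regions[i], sep = "\r"), rkey)
    if (anyNA(idx)) {
      miss <- unique(vessels$flag_state[has][is.na(idx)])
      stop("no allocation rate for (flag, region): ",
           paste(paste(miss, regions[i], sep = "/"), collapse = ", "))
    }
    catch[has] <- catch[has] + e[has] * rates$region$catch_rate_t_per_kwh[idx]
    revenue[has] <- revenue[has] +
      e[has] * rates$region$revenue_rate_usd_per_kwh[idx]
  }
  vessels$catch_t <- catch
  vessels$revenue_usd <- revenue

  tot <- vessel_total_effort(vessels)
  fe <- setNames(rates$flag_effort$effort_kwh, rates$flag_effort$flag_state)
  if (any(!(vessels$flag_state %in% names(fe))))
    stop("no subsidy rate for flag state(s): ",
         paste(unique(vessels$flag_state[!(vessels$flag_state %in% names(fe))]),
               collapse = ", "))
  share <- tot / fe[vessels$flag_state]

  types <- sort(unique(rates$type_shares$subsidy_type))
  tkey <- paste(rates$type_shares$flag_state, rates$type_shares$subsidy_type,
                sep = "\r")
  for (ty in types) {
    idx <- match(paste(vessels$flag_state, ty, sep = "\r"), tkey)
    amount <- ifelse(is.na(idx), 0, rates$type_shares$amount_usd[idx])
    vessels[[paste0("subsidy_usd__", ty)]] <- unname(amount * share)
  }
  vessels
}

#' Effective subsidy value under type multipliers
#'
#' One dollar of one subsidy type does not change fishing effort as much as a
#' dollar of another; effective subsidies rescale nominal amounts by
#' type-specific multipliers before they enter the bioeconomic model. With
#' all multipliers 1 (the shipped default) effective equals nominal.
#'
#' @param subsidies_by_type Named numeric vector of nominal USD by type.
#' @param weights Named numeric multipliers (>= 0), one per present type.
#' @return Effective subsidy total (USD).
#' @export
#' @examples
#' apply_effective_subsidy_weights(c(fuel = 100, buyback = 100),
#'                                 c(fuel = 1, buyback = 0.2))
apply_effective_subsidy_weights <- function(subsidies_by_type, weights) {
  if (length(subsidies_by_type) == 0L) return(0)
  if (any(weights < 0)) stop("effective-subsidy multipliers must be >= 0")
  missing <- setdiff(names(subsidies_by_type), names(weights))
  if (length(missing) > 0L)
    stop("no effective-subsidy multiplier for type(s): ",
         paste(missing, collapse = ", "))
  sum(subsidies_by_type * weights[names(subsidies_by_type)])
}

#' Default effective-subsidy multipliers
#'
#' Unit multipliers for every known subsidy type: effective subsidies equal
#' nominal subsidies unless a weights configuration supplies the
#' normalization derived from empirical work on subsidy effort-effects.
#'
#' @param types Subsidy types to cover (defaults to the full vocabulary).
#' @return Named numeric vector of 1s.
#' @export
default_effective_weights <- function(types = names(capacity_enhancing_types())) {
  setNames(rep(1, length(types)), types)
}

#' Split vessels into managed and open-access tiers
#'
#' Vessels with a management score at or above the empirical quantile of the
#' scores at `quantile_threshold` are labeled `"managed"`; the rest
#' `"open_access"`. The quantile uses the *higher* order-statistic convention
#' (`sorted[ceiling((n - 1) p) + 1]`) and ties at the threshold go to
#' managed, so with distinct scores and the default 0.5 threshold the top
#' half of the fleet is managed.
#'
#' @param vessels A vessel database.
#' @param quantile_threshold Quantile in (0, 1); default 0.5.
#' @return `vessels` with a `management_tier` column.
#' @export
#' @examples
#' v <- worked_example_fixture()$vessels
#' table(assign_management_tier(v)$management_tier)
assign_management_tier <- function(vessels, quantile_threshold = 0.5) {
  if (nrow(vessels) == 0L) stop("cannot assign tiers to an empty vessel set")
  if (quantile_threshold <= 0 || quantile_threshold >= 1)
    stop("quantile_threshold must lie strictly between 0 and 1")
  s <- vessels$management_score
  if (any(s < 0 | s > 1)) stop("management_score must lie in [0, 1]")
  thr <- quantile_higher(s, quantile_threshold)
  vessels$management_tier <- ifelse(s >= thr, "managed", "open_access")
  vessels
}

# Empirical quantile, higher order-statistic convention.
quantile_higher <- function(x, p) {
  xs <- sort(x)
  xs[ceiling((length(x) - 1) * p) + 1L]
}
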