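# Vessel-database schema and validation.
#
# A vessel database is a plain data.frame, one row per vessel. Fishing effort
# is held wide, one column per FAO major fishing area (`effort_kwh__<code>`),
# and allocated subsidies likewise (`subsidy_usd__<type>`). All monetary
# amounts are 2018 USD and are never converted.

# FAO major marine fishing areas.
FAO_AREAS <- c("18", "21", "27", "31", "34", "37", "41", "47", "48", "51",
               "57", "58", "61", "67", "71", "77", "81", "87", "88")

DEVELOPMENT_STATUSES <- c("developed", "developing", "LDC")

VESSEL_DB_VERSION <- "subsidysim_vessel_db v1"
SUBSIDY_TABLE_VERSION <- "subsidysim_subsidy_table v1"

#' Subsidy types and their capacity-enhancing classification
#'
#' The subsidy-type vocabulary used throughout the package. Types that
#' artificially lower fishing costs or raise revenues (fuel, vessel
#' construction, port development, market support) are classified as
#' capacity-enhancing; fisheries-management and buyback programmes are not.
#'
#' @return Named logical vector: `TRUE` where the type is capacity-enhancing.
#' @export
#' @examples
#' capacity_enhancing_types()
capacity_enhancing_types <- function() {
  c(fuel = TRUE, vessel_construction = TRUE, equipment = TRUE,
    port_development = TRUE, market_support = TRUE, tax_exemption = TRUE,
    buyback = FALSE, management = FALSE, research = FALSE)
}

#' Column names holding per-region effort or per-type subsidies
#'
#' @param vessels A vessel database data.frame.
#' @return Character vector of matching column names.
#' @export
effort_columns <- function(vessels) {
  grep("^effort_kwh__", names(vessels), value = TRUE)
}

#' @rdname effort_columns
#' @export
subsidy_columns <- function(vessels) {
  grep("^subsidy_usd__", names(vessels), value = TRUE)
}

effort_col_region <- function(cols) sub("^effort_kwh__", "", cols)
subsidy_col_type <- function(cols) sub("^subsidy_usd__", "", cols)

#' Total fishing effort per vessel
#'
#' Sums the per-region effort columns (kWh) for each vessel.
#'
#' @param vessels A vessel database data.frame.
#' @return Numeric vector, one total per vessel.
#' @export
vessel_total_effort <- function(vessels) {
  cols <- effort_columns(vessels)
  if (length(cols) == 0L) stop("vessel database has no effort_kwh__ columns")
  rowSums(as.matrix(vessels[, cols, drop = FALSE]))
}

#' Validate a vessel database
#'
#' Checks the structural invariants every vessel record must satisfy: positive
#' engine power, non-negative per-region effort with a positive total,
#' high-seas + distant-water + territorial time fractions summing to at most 1,
#' management scores in \[0, 1\], and non-negative monetary amounts.
#'
#' @param vessels A vessel database data.frame.
#' @param allow_empty Accept a zero-row database (default `TRUE`).
#' @return `vessels`, invisibly; errors describe the first violated invariant.
#' @export
validate_vessels <- function(vessels, allow_empty = TRUE) {
  required <- c("vessel_id", "flag_state", "vessel_class", "length_m",
                "gross_tonnage", "engine_power_kw", "high_seas_fraction",
                "distant_water_fraction", "territorial_fraction",
                "disputed_area", "iuu_listed", "stock_status",
                "management_score", "development_status")
  missing <- setdiff(required, names(vessels))
  if (length(missing) > 0L)
    stop("vessel database is missing columns: ", paste(missing, collapse = ", "))
  if (length(effort_columns(vessels)) == 0L)
    stop("vessel database has no effort_kwh__ columns")
  if (nrow(vessels) == 0L) {
    if (!allow_empty) stop("vessel database is empty")
    return(invisible(vessels))
  }
  if (anyDuplicated(vessels$vessel_id))
    stop("vessel_id values are not unique")
  if (any(vessels$engine_power_kw <= 0))
    stop("engine_power_kw must be > 0 for every vessel")
  eff <- as.matrix(vessels[, effort_columns(vessels), drop = FALSE])
  if (any(eff < 0)) stop("per-region effort must be >= 0")
  if (any(rowSums(eff) <= 0)) stop("total effort must be > 0 for every vessel")
  zf <- vessels$high_seas_fraction + vessels$distant_water_fraction +
    vessels$territorial_fraction
  if (any(vessels$high_seas_fraction < 0) || any(vessels$distant_water_fraction < 0) ||
      any(vessels$territorial_fraction < 0))
    stop("zone-time fractions must be >= 0")
  if (any(zf > 1 + 1e-9))
    stop("zone-time fractions must sum to <= 1 per vessel")
  if (any(vessels$management_score < 0 | vessels$management_score > 1))
    stop("management_score must lie in [0, 1]")
  if (any(vessels$stock_status <= 0))
    stop("stock_status must be > 0")
  if (!all(vessels$development_status %in% DEVELOPMENT_STATUSES))
    stop("development_status must be one of: ",
         paste(DEVELOPMENT_STATUSES, collapse = ", "))
  money <- intersect(c("catch_t", "revenue_usd"), names(vessels))
  money <- c(money, subsidy_columns(vessels))
  for (col in money) {
    if (any(vessels[[col]] < 0, na.rm = TRUE))
      stop("monetary/catch column ", col, " must be >= 0")
  }
  invisible(vessels)
}

#' Read and write vessel databases and subsidy tables as CSV
#'
#' The on-disk format is UTF-8 CSV with a versioned header comment line
#' (`# subsidysim_vessel_db v1` / `# subsidysim_subsidy_table v1`). Effort and
#' subsidy maps are stored wide as `effort_kwh__<FAO-code>` and
#' `subsidy_usd__<type>` columns. Writing then reading a database reproduces
#' it exactly.
#'
#' @param vessels,subsidies The data.frame to write.
#' @param path File path.
#' @return Readers return the data.frame; writers return `path` invisibly.
#' @export
write_vessel_database <- function(vessels, path) {
  validate_vessels(vessels)
  write_versioned_csv(vessels, path, VESSEL_DB_VERSION)
}

#' @rdname write_vessel_database
#' @export
read_vessel_database <- function(path) {
  vessels <- read_versioned_csv(path, VESSEL_DB_VERSION)
  vessels$flag_state <- as.character(vessels$flag_state)
  vessels$vessel_id <- as.character(vessels$vessel_id)
  validate_vessels(vessels)
  vessels
}

#' @rdname write_vessel_database
#' @export
write_subsidy_table <- function(subsidies, path) {
  validate_subsidy_table(subsidies)
  write_versioned_csv(subsidies, path, SUBSIDY_TABLE_VERSION)
}

#' @rdname write_vessel_database
#' @export
read_subsidy_table <- function(path) {
  tab <- read_versioned_csv(path, SUBSIDY_TABLE_VERSION)
  tab$flag_state <- as.character(tab$flag_state)
  tab$subsidy_type <- as.character(tab$subsidy_type)
  validate_subsidy_table(tab)
  tab
}

write_versioned_csv <- function(df, path, version) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", version), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_versioned_csv <- function(path, version) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!identical(first, paste0("# ", version)))
    stop("file ", path, " does not carry the expected header '", version, "'")
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
           encoding = "UTF-8")
}

#' Validate a country subsidy table
#'
#' One row per (flag state, subsidy type) with a non-negative USD amount and a
#' capacity-enhancing flag.
#'
#' @param subsidies A subsidy-table data.frame.
#' @return `subsidies`, invisibly.
#' @export
validate_subsidy_table <- function(subsidies) {
  required <- c("flag_state", "subsidy_type", "amount_usd", "capacity_enhancing")
  missing <- setdiff(required, names(subsidies))
  if (length(missing) > 0L)
    stop("subsidy table is missing columns: ", paste(missing, collapse = ", "))
  if (any(subsidies$amount_usd < 0))
    stop("subsidy amount_usd must be >= 0")
  if (anyDuplicated(subsidies[, c("flag_state", "subsidy_type")]))
    stop("subsidy table has duplicate (flag_state, subsidy_type) rows")
  invisible(subsidies)
}
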