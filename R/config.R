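# Structured configuration files (JSON or YAML by extension).
#
# One file per concern -- model parameters, effective-subsidy weights,
# proposal -- so proposals can be swapped on the command line. Readers
# validate against the constructors and report the offending field.

read_structured <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported configuration format '.", ext, "' for ", path,
         " (use .json or .yaml)")
  }
}

#' Read model parameters from a configuration file
#'
#' The file (JSON or YAML) holds the fields of [model_params()]; unknown
#' fields are rejected so typos surface as errors.
#'
#' @param path Path to a `.json`/`.yaml` file.
#' @return A [model_params()] object.
#' @export
read_model_params <- function(path) {
  raw <- read_structured(path)
  allowed <- names(formals(model_params))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L)
    stop("unknown model-parameter field(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(model_params, raw)
}

#' Read effective-subsidy multipliers from a configuration file
#'
#' A flat mapping subsidy type -> non-negative multiplier.
#'
#' @param path Path to a `.json`/`.yaml` file.
#' @return Named numeric vector.
#' @export
read_effective_weights <- function(path) {
  raw <- read_structured(path)
  if (!is.null(raw$multiplier)) raw <- raw$multiplier
  w <- unlist(raw)
  if (is.null(names(w)) || !is.numeric(w))
    stop("weights file ", path, " must map subsidy types to numbers")
  if (any(w < 0))
    stop("field 'multiplier' in ", path, " must be >= 0 for every type")
  w
}

#' Read a reform proposal from a configuration file
#'
#' The file holds `name`, a list of `disciplines` (each with the fields of
#' [discipline()]) and optionally `cap_rule` (the fields of [cap_rule()]).
#'
#' @param path Path to a `.json`/`.yaml` file.
#' @return A [proposal()] object.
#' @export
read_proposal <- function(path) {
  raw <- read_structured(path)
  if (is.null(raw$name)) stop("proposal file ", path, " lacks field 'name'")
  disc <- lapply(raw$disciplines, function(d) {
    allowed <- names(formals(discipline))
    unknown <- setdiff(names(d), allowed)
    if (length(unknown) > 0L)
      stop("unknown discipline field(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    d$listed_types <- unlist(d$listed_types)
    d$statuses <- unlist(d$statuses)
    d$exempt_development <- if (is.null(d$exempt_development)) character(0)
                            else unlist(d$exempt_development)
    do.call(discipline, d)
  })
  cr <- NULL
  if (!is.null(raw$cap_rule)) {
    r <- raw$cap_rule
    cr <- cap_rule(tier_by_status = unlist(r$tier_by_status),
                   cap_basis = r$cap_basis,
                   cap_percent_by_tier = unlist(r$cap_percent_by_tier),
                   green_box_types = if (is.null(r$green_box_types)) character(0)
                                     else unlist(r$green_box_types))
  }
  proposal(name = raw$name, disciplines = disc, cap_rules = cr)
}

#' Paths to the shipped example configurations
#'
#' The package ships a small library of example proposal files named after
#' the main families of reform packages under negotiation (IUU list
#' prohibition, overfished-stock rules at two stringency levels, high-seas
#' thresholds, a cap-and-tier example and the ambitious full removal of
#' capacity-enhancing subsidies), plus default model parameters and unit
#' effective-subsidy weights.
#'
#' @param file Optional file name below `extdata/`; when omitted, lists the
#'   available files.
#' @return A path, or a character vector of available files.
#' @export
#' @examples
#' example_config()
example_config <- function(file = NULL) {
  base <- system.file("extdata", package = "subsidysim")
  if (is.null(file))
    return(list.files(base, recursive = TRUE))
  path <- file.path(base, file)
  if (!file.exists(path)) stop("no shipped configuration named ", file)
  path
}
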