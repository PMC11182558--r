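# Scenario files (YAML key-value), trajectory / sweep / summary
# serialization, and the packaged baseline scenario. Units are fixed
# package-wide (persons, days) and are not configurable.

SCENARIO_SCHEMA <- 1L

scenario_field_docs <- c(
  schema = "scenario schema version",
  lambda1 = "government-response effect (fraction, 0-1)",
  lambda2 = "emotional-guidance effect (fraction, 0-1)",
  lambda3 = "heat-reduction effect (fraction, 0-1)",
  lambda4 = "event-coupling effect (fraction, 0-1)",
  lambda5 = "user risk propensity (fraction of entrants, 0-1)",
  lambda6 = "information uncertainty (fraction, 0-1)",
  T_c = "opinion-conversion time (days)",
  T_e = "extreme-opinion formation time (days)",
  T_ef = "extreme-opinion extinction time (days)",
  T_pi = "positive-opinion interaction time (days)",
  T_ni = "negative-opinion interaction time (days)",
  S0 = "initial user pool (persons)",
  horizon = "simulation horizon (days)",
  dt = "Euler step size (days)",
  mode = "meanfield | stochastic",
  seed = "RNG seed (integer; stochastic mode)",
  strict_integer = "floor opinion allocations to whole persons",
  epsilon = "denominator guard while NE = 0 (persons)",
  heat_threshold = "NE level that latches heat reduction on (persons)",
  ratio_cap = "cap on the NIN/NE escalation ratio",
  delay_fraction = "fraction of entrants present at t = 0",
  entry_time = "mean delayed-entry time (days)",
  exit_scale_days = "lifecycle exit-hazard scale (days)"
)

config_to_fields <- function(config) {
  c(list(schema = SCENARIO_SCHEMA),
    unclass(config$params),
    config[setdiff(names(config), "params")])
}

fields_to_config <- function(fields) {
  par_names <- names(formals(gp_params))
  cfg_names <- setdiff(names(formals(gp_config)), "params")
  pars <- fields[intersect(names(fields), par_names)]
  rest <- fields[intersect(names(fields), cfg_names)]
  do.call(gp_config, c(list(params = do.call(gp_params, pars)), rest))
}

#' Write a scenario file
#'
#' Serialises a [gp_config()] as a flat, schema-versioned YAML
#' key-value document with the unit of every field documented in a
#' comment. Numeric fields are written with full round-trip precision.
#'
#' @param config A [gp_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_scenario()], [baseline_scenario()]
#' @export
write_scenario <- function(config, path) {
  validate_gp_config(config)
  fields <- config_to_fields(config)
  fmt <- function(v) {
    if (is.character(v)) v
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
  lines <- c(
    "# gpsim scenario file: all quantities in persons and days",
    vapply(names(fields), function(k) {
      sprintf("%s: %s  # %s", k, fmt(fields[[k]]),
              scenario_field_docs[[k]])
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a scenario file
#'
#' Parses a YAML scenario file into a [gp_config()]. Unknown keys are
#' rejected; missing keys are filled from the documented defaults with
#' a logged notice.
#'
#' @param path Scenario file path.
#' @return A [gp_config()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("scenario file not found: %s", path))
  }
  fields <- yaml::read_yaml(path)
  known <- names(scenario_field_docs)
  unknown <- setdiff(names(fields), known)
  if (length(unknown)) {
    abort(sprintf("unknown scenario key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  schema <- fields$schema %||% SCENARIO_SCHEMA
  if (schema != SCENARIO_SCHEMA) {
    abort(sprintf("unsupported scenario schema %s (this build reads %d)",
                  format(schema), SCENARIO_SCHEMA))
  }
  missing <- setdiff(setdiff(known, "schema"), names(fields))
  if (length(missing)) {
    inform(sprintf("scenario: filling missing key(s) from defaults: %s",
                   paste(missing, collapse = ", ")))
  }
  fields$schema <- NULL
  fields_to_config(fields)
}

#' The packaged baseline scenario
#'
#' The calibrated case-study scenario shipped with the package (a
#' COVID-19-era drug-approval controversy): 100 initial users,
#' `lambda1 = lambda2 = 0.2`, `lambda3 = 0.4`, `lambda4 = 0.9`,
#' `lambda5 = 0.2`, `lambda6 = 0.5`, time constants
#' `T_c = 2, T_e = 6, T_ef = 7, T_pi = 3, T_ni = 1` days, a 100-day
#' mean-field run at `dt = 0.05`, and the documented defaults for all
#' numerical fields.
#'
#' @return A [gp_config()].
#' @examples
#' baseline_scenario()$params$lambda3
#' @export
baseline_scenario <- function() {
  path <- system.file("extdata", "baseline_scenario.yaml",
                      package = "gpsim", mustWork = TRUE)
  suppressMessages(read_scenario(path))
}

#' Write / read a trajectory as delimited text
#'
#' Comma-delimited with a mandatory header; doubles are written in
#' shortest round-trip representation, so write -> read is the exact
#' inverse. Reading validates the header and fails on non-numeric
#' cells with the offending line number.
#'
#' @param trajectory A [run_gp()] trajectory.
#' @param path File path.
#' @param flows Keep the flow columns (default) or only the state
#'   columns.
#' @return `write_trajectory()`: `path`, invisibly.
#'   `read_trajectory()`: a `gp_trajectory` tibble (without the
#'   generating config attached).
#' @export
write_trajectory <- function(trajectory, path, flows = TRUE) {
  tbl <- as_tibble(trajectory)
  if (!flows) tbl <- tbl[, names(.S)[1:11], drop = FALSE]
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tbl <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_double()
  )))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf("parse error in %s at line %d: expected %s, got %s",
                  path, probs$row[1L], probs$expected[1L],
                  probs$actual[1L]))
  }
  required <- names(.S)[1:11]
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(sprintf("malformed trajectory header: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  structure(tbl, class = c("gp_trajectory", class(tbl)))
}

#' Write a sweep table / summary report
#'
#' A sweep serialises as a comma-delimited table (parameter value, NE
#' peak and timing, NE half-decay, NIN peak and timing, final totals);
#' a summary serialises as a flat tab-delimited report with one record
#' per compartment. Raw values are kept at full precision;
#' presentation rounding is left to reports.
#'
#' @param sweep A [oat_sweep()] result.
#' @param summary A [summarize_trajectory()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  readr::write_csv(as_tibble(sweep), path)
  invisible(path)
}

#' @rdname write_sweep
#' @export
write_summary <- function(summary, path) {
  readr::write_tsv(summary, path)
  invisible(path)
}
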