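#' Model parameters for the group-polarization opinion field
#'
#' Bundles the exogenous knobs of the stock-and-flow model: six
#' dimensionless modulation fractions (`lambda1`--`lambda6`), five time
#' constants (days) and the initial user pool. All quantities are in
#' persons and days; there are no configurable units.
#'
#' @param lambda1 Government-response effect. Fraction of the initial
#'   pool that never enters the opinion field because of timely official
#'   response; in `[0, 1]`.
#' @param lambda2 Emotional-guidance effect. Strength of authority-led
#'   messaging that moves negatively-opinioned interacting users towards
#'   positive or non-extreme states; in `[0, 1]`.
#' @param lambda3 Heat-reduction effect. Strength of traffic-limiting
#'   measures that convert extreme-opinion users back to non-extreme
#'   ones; active only once extreme opinions exist; in `[0, 1]`.
#' @param lambda4 Event-coupling effect. Stereotype-forming influence of
#'   concurrent events that accelerates conversion to extreme opinions;
#'   in `[0, 1]`.
#' @param lambda5 User risk propensity. Fraction of entrants predisposed
#'   to form a negative opinion; in `[0, 1]`.
#' @param lambda6 Information uncertainty. Ambiguity of event
#'   information that drives opinion holders into interactive
#'   discussion; in `[0, 1]`.
#' @param T_c Opinion-conversion time (days): time to switch between
#'   positive and negative opinion under interaction.
#' @param T_e Extreme-opinion formation time (days).
#' @param T_ef Extreme-opinion extinction time (days).
#' @param T_pi Interaction time of positive-opinion users (days).
#' @param T_ni Interaction time of negative-opinion users (days).
#' @param S0 Initial user pool (persons) attending the emergency before
#'   the government-response filter is applied.
#'
#' @return An object of class `gp_params` (a named list).
#' @seealso [gp_config()], [baseline_scenario()]
#' @examples
#' gp_params(lambda3 = 0.9)
#' @export
gp_params <- function(lambda1 = 0.2, lambda2 = 0.2, lambda3 = 0.4,
                      lambda4 = 0.9, lambda5 = 0.2, lambda6 = 0.5,
                      T_c = 2, T_e = 6, T_ef = 7, T_pi = 3, T_ni = 1,
                      S0 = 100) {
  p <- list(
    lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
    lambda4 = lambda4, lambda5 = lambda5, lambda6 = lambda6,
    T_c = T_c, T_e = T_e, T_ef = T_ef, T_pi = T_pi, T_ni = T_ni,
    S0 = S0
  )
  validate_gp_params(p)
  structure(p, class = "gp_params")
}

validate_gp_params <- function(p) {
  lam <- unlist(p[paste0("lambda", 1:6)])
  tt <- unlist(p[c("T_c", "T_e", "T_ef", "T_pi", "T_ni")])
  if (any(!is.finite(lam)) || any(lam < 0) || any(lam > 1)) {
    abort("each `lambda` must be a finite fraction in [0, 1]")
  }
  if (any(!is.finite(tt)) || any(tt <= 0)) {
    abort("each time constant `T_*` must be finite and strictly positive (days)")
  }
  if (!is.finite(p$S0) || p$S0 < 0) {
    abort("`S0` must be a finite non-negative number of persons")
  }
  invisible(p)
}

#' @export
print.gp_params <- function(x, ...) {
  cat("<gp_params>\n")
  cat(sprintf("  lambda1..6: %s\n",
              paste(format(unlist(x[paste0("lambda", 1:6)])), collapse = " ")))
  cat(sprintf("  T_c=%g T_e=%g T_ef=%g T_pi=%g T_ni=%g (days)\n",
              x$T_c, x$T_e, x$T_ef, x$T_pi, x$T_ni))
  cat(sprintf("  S0=%g persons\n", x$S0))
  invisible(x)
}

#' Simulation configuration
#'
#' Couples a [gp_params()] set with the numerical and mechanistic
#' choices of a run: horizon, Euler step, mean-field vs stochastic
#' gating, entry schedule, guards and the lifecycle exit-hazard scale.
#'
#' @param params A [gp_params()] object.
#' @param horizon Simulation horizon (days).
#' @param dt Euler step size (days).
#' @param mode `"meanfield"` (deterministic; every random gate replaced
#'   by its expectation) or `"stochastic"` (opinion allocation drawn
#'   multinomially, the event-coupling gate drawn Bernoulli).
#' @param seed Integer RNG seed used by stochastic runs.
#' @param strict_integer If `TRUE`, mean-field opinion allocations are
#'   floored to whole persons each step (fidelity experiments with the
#'   integer-division reading of the allocation rule).
#' @param epsilon Small positive guard (persons) replacing `NE` in
#'   denominators while no extreme opinions exist.
#' @param heat_threshold Extreme-opinion level (persons) that, once
#'   first exceeded, latches the heat-reduction pathway on.
#' @param ratio_cap Upper bound on the `NIN/NE` ratio inside the
#'   escalation flow, bounding the quadratic term at start-up.
#' @param delay_fraction Fraction of entrants present at `t = 0`; the
#'   remainder trickles in at exponential rate `1/entry_time`.
#' @param entry_time Mean delayed-entry time (days).
#' @param exit_scale_days Normalisation constant (days) of the
#'   lifecycle exit hazard `h(t) = t / exit_scale_days`. The default is
#'   a one-time calibration placing the baseline extreme-opinion peak
#'   at day 20; see the package vignette.
#'
#' @return An object of class `gp_config` (a named list).
#' @examples
#' cfg <- gp_config(gp_params(), horizon = 50)
#' @export
gp_config <- function(params = gp_params(), horizon = 100, dt = 0.025,
                      mode = c("meanfield", "stochastic"), seed = 1L,
                      strict_integer = FALSE, epsilon = 1e-9,
                      heat_threshold = 1, ratio_cap = 10,
                      delay_fraction = 0.5, entry_time = 3,
                      exit_scale_days = 365) {
  mode <- match.arg(mode)
  if (!inherits(params, "gp_params")) {
    params <- do.call(gp_params, as.list(params))
  }
  cfg <- structure(list(
    params = params, horizon = horizon, dt = dt, mode = mode,
    seed = as.integer(seed), strict_integer = isTRUE(strict_integer),
    epsilon = epsilon, heat_threshold = heat_threshold,
    ratio_cap = ratio_cap, delay_fraction = delay_fraction,
    entry_time = entry_time, exit_scale_days = exit_scale_days
  ), class = "gp_config")
  validate_gp_config(cfg)
  cfg
}

validate_gp_config <- function(cfg) {
  validate_gp_params(cfg$params)
  if (!is.finite(cfg$dt) || cfg$dt <= 0) abort("`dt` must be > 0 (days)")
  if (!is.finite(cfg$horizon) || cfg$horizon < cfg$dt) {
    abort("`horizon` must be at least one step (`dt`) long")
  }
  if (!is.finite(cfg$epsilon) || cfg$epsilon <= 0) abort("`epsilon` must be > 0")
  if (!is.finite(cfg$delay_fraction) || cfg$delay_fraction < 0 ||
      cfg$delay_fraction > 1) {
    abort("`delay_fraction` must lie in [0, 1]")
  }
  if (!is.finite(cfg$entry_time) || cfg$entry_time <= 0) {
    abort("`entry_time` must be > 0 (days)")
  }
  if (!is.finite(cfg$exit_scale_days) || cfg$exit_scale_days <= 0) {
    abort("`exit_scale_days` must be > 0 (days)")
  }
  if (!is.finite(cfg$heat_threshold) || cfg$heat_threshold < 0) {
    abort("`heat_threshold` must be >= 0 (persons)")
  }
  if (!is.finite(cfg$ratio_cap) || cfg$ratio_cap <= 0) {
    abort("`ratio_cap` must be > 0")
  }
  if (!is.element(cfg$mode, c("meanfield", "stochastic"))) {
    abort("`mode` must be \"meanfield\" or \"stochastic\"")
  }
  invisible(cfg)
}

#' @export
print.gp_config <- function(x, ...) {
  cat("<gp_config>\n")
  print(x$params)
  cat(sprintf("  horizon=%g days, dt=%g, mode=%s, seed=%d\n",
              x$horizon, x$dt, x$mode, x$seed))
  cat(sprintf("  entry: %g at t=0, rest ~ Exp(mean %g d); exit scale %g d\n",
              x$delay_fraction, x$entry_time, x$exit_scale_days))
  invisible(x)
}

#' Names of the opinion compartments
#'
#' The seven opinion states plus the undecided pool, in recording order:
#' `undecided` (attending, opinion unformed), `P` (positive, not
#' interacting), `PI` (positive, interacting), `PIP` (kept a positive
#' opinion after interaction; terminal), `N` (negative, not
#' interacting), `NI` (negative, interacting), `NE` (negative extreme),
#' `NIN` (negative non-extreme).
#'
#' @return Character vector of compartment names.
#' @export
gp_compartments <- function() {
  c("undecided", "P", "PI", "PIP", "N", "NI", "NE", "NIN")
}

# Names of parameters that a one-at-a-time sweep may vary.
sweepable_params <- function() {
  c(paste0("lambda", 1:6), "T_c", "T_e", "T_ef", "T_pi", "T_ni")
}

# Domain check for a single parameter value; used before any sweep run.
param_in_domain <- function(name, value) {
  if (grepl("^lambda", name)) {
    is.finite(value) & value >= 0 & value <= 1
  } else {
    is.finite(value) & value > 0
  }
}
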