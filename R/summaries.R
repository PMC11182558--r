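# Scalar statistics read off trajectories: peaks, fractional-decay
# times, percent reductions, and the polarization risk indicator
# (the peak of the negative-extreme stock NE).

check_compartment <- function(trajectory, compartment) {
  ok <- compartment %in% names(trajectory)
  if (!all(ok)) {
    abort(sprintf(
      "unknown compartment%s: %s (known: %s)",
      if (sum(!ok) > 1) "s" else "",
      paste(compartment[!ok], collapse = ", "),
      paste(gp_compartments(), collapse = ", ")
    ))
  }
  invisible(compartment)
}

#' Peak value and peak time of a compartment
#'
#' Finds the earliest global maximum of the named stock(s) on the
#' recorded time grid (ties broken to the earliest time).
#'
#' @param trajectory A [run_gp()] trajectory (or any tibble with a `t`
#'   column and the named compartment columns).
#' @param compartment Compartment name(s), see [gp_compartments()].
#'
#' @return A tibble with columns `compartment`, `t_peak` (days) and
#'   `peak` (persons), one row per requested compartment.
#' @examples
#' peak(run_gp(gp_config(horizon = 40)), "NE")
#' @export
peak <- function(trajectory, compartment = "NE") {
  if (nrow(trajectory) == 0) abort("trajectory has no records")
  check_compartment(trajectory, compartment)
  tibble(
    compartment = compartment,
    t_peak = map_dbl(compartment, function(cc) {
      trajectory$t[which.max(trajectory[[cc]])]
    }),
    peak = map_dbl(compartment, function(cc) max(trajectory[[cc]]))
  )
}

#' Time for a stock to decay to a fraction of its peak
#'
#' First time after the peak at which the stock has fallen to
#' `fraction` of its peak value, linearly interpolated between grid
#' points. `NA` if the stock never falls that far within the horizon,
#' or if the peak is zero.
#'
#' @inheritParams peak
#' @param compartment A single compartment name.
#' @param fraction Target level as a fraction of the peak, in `(0, 1)`;
#'   `0.5` gives the half-decay time.
#'
#' @return Time in days (scalar), or `NA`.
#' @examples
#' decay_time(run_gp(gp_config(horizon = 80)), "NE", 0.5)
#' @export
decay_time <- function(trajectory, compartment = "NE", fraction = 0.5) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1")
  }
  if (nrow(trajectory) == 0) abort("trajectory has no records")
  check_compartment(trajectory, compartment)
  x <- trajectory[[compartment]]
  tt <- trajectory$t
  i0 <- which.max(x)
  pk <- x[i0]
  if (pk <= 0) return(NA_real_)
  target <- fraction * pk
  after <- seq(i0, length(x))
  j_rel <- which(x[after] <= target)[1L]
  if (is.na(j_rel)) return(NA_real_)
  j <- after[j_rel]
  # linear interpolation on the segment crossing the target
  t1 <- tt[j - 1L]; t2 <- tt[j]
  v1 <- x[j - 1L]; v2 <- x[j]
  t1 + (v1 - target) / (v1 - v2) * (t2 - t1)
}

#' Percent reduction between two peak levels
#'
#' Convention fixed to `100 * (reference - comparison) / reference`,
#' with `reference` the larger (worst-case) level, so that a reduction
#' reads as a positive percentage.
#'
#' @param reference Reference (worst-case) level, `> 0`.
#' @param comparison Level being compared.
#'
#' @return Percent reduction (vectorised).
#' @examples
#' percent_reduction(626, 472)
#' @export
percent_reduction <- function(reference, comparison) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    abort("`reference` must be finite and > 0")
  }
  100 * (reference - comparison) / reference
}

#' Per-compartment trajectory summary
#'
#' Peak value and time, fractional-decay time and end-of-horizon value
#' for each compartment. `tidy()` on a trajectory is an alias. The
#' polarization risk indicator of a run is the `NE` peak (see
#' [glance.gp_trajectory()]).
#'
#' @inheritParams peak
#' @param compartments Compartments to summarise.
#' @param fraction Decay fraction passed to [decay_time()].
#'
#' @return A tibble with one row per compartment: `compartment`,
#'   `peak`, `t_peak`, `decay_t` (days to reach `fraction` of peak;
#'   `NA` if never) and `final` (value at the last record).
#' @examples
#' summarize_trajectory(run_gp(gp_config(horizon = 40)))
#' @export
summarize_trajectory <- function(trajectory,
                                 compartments = gp_compartments(),
                                 fraction = 0.5) {
  pk <- peak(trajectory, compartments)
  tibble(
    compartment = compartments,
    peak = pk$peak,
    t_peak = pk$t_peak,
    decay_t = map_dbl(compartments, function(cc) {
      decay_time(trajectory, cc, fraction)
    }),
    final = map_dbl(compartments, function(cc) {
      tail(trajectory[[cc]], 1L)
    })
  )
}

#' @rdname summarize_trajectory
#' @param x A `gp_trajectory`.
#' @param ... Passed on to [summarize_trajectory()].
#' @method tidy gp_trajectory
#' @export
tidy.gp_trajectory <- function(x, ...) summarize_trajectory(x, ...)

#' One-row summary of a run
#'
#' The headline numbers of a simulation: the group-polarization risk
#' indicator (peak of the negative-extreme stock `NE`), its timing and
#' half-decay, and the entry/exit totals.
#'
#' @param x A `gp_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: `gp_risk` (persons), `ne_peak_day`,
#'   `ne_half_decay_day` (days, `NA` if not reached), `entered_total`,
#'   `exited_total` (persons), `horizon` (days) and `mode`.
#' @method glance gp_trajectory
#' @export
glance.gp_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  ne <- peak(x, "NE")
  tibble(
    gp_risk = ne$peak,
    ne_peak_day = ne$t_peak,
    ne_half_decay_day = decay_time(x, "NE", 0.5),
    entered_total = tail(x$entered_cum, 1L),
    exited_total = tail(x$exited_cum, 1L),
    horizon = if (!is.null(cfg)) cfg$horizon else max(x$t),
    mode = if (!is.null(cfg)) cfg$mode else NA_character_
  )
}
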