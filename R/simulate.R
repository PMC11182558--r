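# Simulator: full trajectories and replicate ensembles.

# Core engine: repeated flows_raw() + step_raw() on the internal vector
# state, with mid-run validation every step. Returns the raw recording
# matrix (states and flows).
run_engine <- function(config, record = c("step", "daily")) {
  record <- match.arg(record)
  pr <- config$params
  dt <- config$dt
  n_steps <- round(config$horizon / dt)
  stochastic <- config$mode == "stochastic"

  entrants <- (1 - pr$lambda1) * pr$S0
  u0 <- config$delay_fraction * entrants
  s <- numeric(13L)
  s[.S["undecided"]] <- u0
  s[.S["entered_cum"]] <- u0
  s[.S["pending"]] <- entrants - u0

  keep_every <- 1L
  if (record == "daily") {
    per_day <- 1 / dt
    if (abs(per_day - round(per_day)) > 1e-9) {
      abort("daily recording needs `dt` to divide one day evenly")
    }
    keep_every <- as.integer(round(per_day))
  }
  kept <- seq(0L, n_steps, by = keep_every)
  out <- matrix(NA_real_, nrow = length(kept), ncol = 11L + 19L)
  colnames(out) <- c(names(.S)[1:11], names(.F))

  tol <- 1e-8
  row <- 1L
  for (i in 0:n_steps) {
    f <- flows_raw(s, pr, config, stochastic = stochastic)
    if (i %% keep_every == 0L) {
      out[row, 1:11] <- s[1:11]
      out[row, 12:30] <- f
      row <- row + 1L
    }
    # mid-run validation (cheap; every step)
    stocks <- s[2:9]
    bad <- which(!is.finite(stocks) | stocks < 0)
    if (length(bad)) {
      abort(sprintf(
        "invalid state at t = %.4g days: stock `%s` is %s",
        s[1L], names(.S)[1L + bad[1L]], format(stocks[bad[1L]])
      ))
    }
    balance <- sum(stocks) + s[10L] - s[11L]
    if (abs(balance) > tol * max(s[11L], 1)) {
      abort(sprintf(
        "conservation violated at t = %.4g days (imbalance %.3g persons)",
        s[1L], balance
      ))
    }
    if (i < n_steps) s <- step_raw(s, f, pr, config)
  }
  out
}

new_gp_trajectory <- function(mat, config) {
  tbl <- as_tibble(as.data.frame(mat))
  structure(tbl,
            config = config,
            class = c("gp_trajectory", class(tbl)))
}

#' Run one simulation
#'
#' Integrates the model with explicit Euler steps of `config$dt` over
#' `[0, horizon]`, starting from an empty opinion field with
#' `delay_fraction * (1 - lambda1) * S0` users undecided at `t = 0` and
#' the remainder entering at exponential rate `1/entry_time`. Every
#' recorded row carries the full state and the instantaneous flows, so
#' summary quantities can be recomputed post hoc without re-running.
#' State validity (finiteness, non-negativity, conservation of persons
#' to 1e-8 relative) is checked at every step and a violation aborts
#' with the offending stock and time.
#'
#' In `"stochastic"` mode the RNG is seeded from `config$seed` at the
#' start of the run, so identical configurations give identical
#' trajectories.
#'
#' @param config A [gp_config()].
#' @param record `"step"` (default) records every Euler step,
#'   `"daily"` keeps one row per day.
#'
#' @return A `gp_trajectory`: a tibble with one row per recorded time
#'   and columns `t`, the compartments ([gp_compartments()]),
#'   `exited_cum`, `entered_cum`, and the flow columns of
#'   [compute_flows()]; the generating config is attached as attribute
#'   `"config"`.
#' @examples
#' traj <- run_gp(gp_config(horizon = 30))
#' dplyr::filter(traj, t %in% c(0, 10, 20, 30))
#' @export
run_gp <- function(config, record = c("step", "daily")) {
  validate_gp_config(config)
  if (config$mode == "stochastic") set.seed(config$seed)
  new_gp_trajectory(run_engine(config, record), config)
}

#' @export
print.gp_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<gp_trajectory> %d records over %g days (mode %s)\n",
              nrow(x), cfg$horizon, cfg$mode))
  NextMethod()
}

#' Run a replicate ensemble
#'
#' Runs `n_replicates` independent stochastic trajectories from one
#' configuration. Child seeds are derived deterministically from the
#' root `config$seed`, so the whole ensemble is reproducible; replicate
#' `i` of an ensemble equals a single [run_gp()] with the i-th child
#' seed.
#'
#' @param config A [gp_config()] with `mode = "stochastic"`. A
#'   mean-field config with `n_replicates > 1` warns and returns a
#'   single run (the replicates would be identical).
#' @param n_replicates Number of replicates (`>= 1`).
#' @param record Recording cadence per replicate; `"daily"` (default)
#'   keeps ensembles of hundreds of replicates small.
#'
#' @return A `gp_ensemble`: a list of `gp_trajectory` objects with the
#'   shared config, replicate count and child seeds attached.
#' @examples
#' cfg <- gp_config(mode = "stochastic", horizon = 20, seed = 7)
#' ens <- run_ensemble(cfg, 3)
#' length(ens)
#' @export
run_ensemble <- function(config, n_replicates,
                         record = c("daily", "step")) {
  record <- match.arg(record)
  validate_gp_config(config)
  if (n_replicates < 1) abort("`n_replicates` must be >= 1")
  if (config$mode != "stochastic") {
    if (n_replicates > 1) {
      warn("mean-field replicates are identical; returning a single run")
    }
    trajs <- list(run_gp(config, record = record))
    seeds <- config$seed
  } else {
    set.seed(config$seed)
    seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
    trajs <- map(seeds, function(sd) {
      cfg_i <- config
      cfg_i$seed <- sd
      run_gp(cfg_i, record = record)
    })
  }
  structure(trajs,
            config = config, n_replicates = length(trajs),
            child_seeds = seeds,
            class = "gp_ensemble")
}

#' @export
print.gp_ensemble <- function(x, ...) {
  cat(sprintf("<gp_ensemble> %d replicates (root seed %d)\n",
              attr(x, "n_replicates"), attr(x, "config")$seed))
  invisible(x)
}

#' Pointwise ensemble mean trajectory
#'
#' Averages every state and flow column across the replicates of an
#' ensemble, on their shared time grid.
#'
#' @param ensemble A [run_ensemble()] result.
#' @return A `gp_trajectory` tibble of column means.
#' @export
ensemble_mean <- function(ensemble) {
  stopifnot(inherits(ensemble, "gp_ensemble"))
  mats <- map(ensemble, function(tr) as.matrix(as_tibble(tr)))
  mean_mat <- Reduce(`+`, mats) / length(mats)
  new_gp_trajectory(mean_mat, attr(ensemble, "config"))
}
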