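# Shared fixtures: all built in code at test time.

# report the whole suite even when one file accumulates many failures
options(testthat.progress.max_fails = Inf)

# small, fast configuration for property tests
quick_config <- function(..., horizon = 20, dt = 0.1) {
  gp_config(gp_params(...), horizon = horizon, dt = dt)
}

# a random valid configuration (caller controls the RNG seed)
random_config <- function(mode = "meanfield") {
  gp_config(
    gp_params(
      lambda1 = runif(1), lambda2 = runif(1), lambda3 = runif(1),
      lambda4 = runif(1), lambda5 = runif(1), lambda6 = runif(1),
      T_c = runif(1, 0.5, 8), T_e = runif(1, 0.5, 8),
      T_ef = runif(1, 0.5, 8), T_pi = runif(1, 0.5, 8),
      T_ni = runif(1, 0.5, 8), S0 = runif(1, 0, 500)
    ),
    horizon = 20, dt = 0.1, mode = mode,
    seed = sample.int(1e6, 1),
    delay_fraction = runif(1), entry_time = runif(1, 0.5, 5),
    exit_scale_days = runif(1, 30, 600),
    heat_threshold = runif(1, 0, 3)
  )
}

# worst-case conservation imbalance over all records of a trajectory
max_imbalance <- function(traj) {
  stocks <- as.matrix(traj[, gp_compartments()])
  max(abs(rowSums(stocks) + traj$exited_cum - traj$entered_cum))
}
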