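test_that("a step with no flows and no entries only advances time", {
  cfg <- gp_config()
  st <- gp_state(t = 2, P = 5, NE = 3, pending = 0)
  f <- compute_flows(gp_state(), cfg$params, cfg) # all-zero flow set
  out <- gp_step(st, cfg$params, cfg, f)
  expect_equal(out$t, st$t + cfg$dt)
  for (cc in gp_compartments()) expect_equal(out[[cc]], st[[cc]])
  expect_equal(out$entered_cum, st$entered_cum)
})

test_that("one step reproduces an independent per-stock ledger", {
  cfg <- gp_config(dt = 0.1)
  pr <- cfg$params
  st <- gp_state(t = 4, undecided = 8, P = 20, PI = 12, N = 6, NI = 9,
                 NE = 5, NIN = 11, pending = 10, heat_active = TRUE)
  f <- compute_flows(st, pr, cfg)
  out <- gp_step(st, pr, cfg, f)

  # brute-force bookkeeping, written out term by term
  dt <- 0.1
  Sn <- f$entry_neg * dt; Sp <- f$entry_pos * dt
  entry <- st$pending / cfg$entry_time
  expect_equal(out$undecided, st$undecided - Sn - Sp + dt * entry)
  expect_equal(out$P, st$P + Sp - dt * (f$v1 + f$exit_P))
  expect_equal(out$PI,
               st$PI + dt * (f$v1 + f$v5 - f$v6 - f$v7 - f$exit_PI_to_PIP))
  expect_equal(out$PIP, st$PIP + dt * f$exit_PI_to_PIP)
  expect_equal(out$N, st$N + Sn - dt * (f$v3 + f$exit_N))
  expect_equal(out$NI, st$NI + dt * (f$v3 - f$v4 - f$v5 - f$v9 - f$exit_NI))
  expect_equal(out$NE,
               st$NE + dt * (f$v4 + f$v7 + f$v10 - f$v11 - f$exit_NE))
  expect_equal(out$NIN,
               st$NIN + dt * (f$v9 + f$v6 + f$v11 - f$v10 - f$exit_NIN))
  expect_equal(out$exited_cum,
               st$exited_cum + dt * (f$exit_P + f$exit_N + f$exit_NI +
                                       f$exit_NIN + f$exit_NE))
  expect_equal(out$entered_cum, st$entered_cum + dt * entry)
  expect_equal(out$pending, st$pending - dt * entry)
})

test_that("excess outflow is rescaled so the stock lands exactly at 0", {
  # N's interaction outflow alone would remove ~5x the stock in one step
  cfg <- gp_config(gp_params(lambda6 = 1, T_ni = 0.1), dt = 0.5)
  pr <- cfg$params
  st <- gp_state(t = 1, N = 0.2, pending = 0)
  f <- compute_flows(st, pr, cfg)
  out <- gp_step(st, pr, cfg, f)
  expect_equal(out$N, 0)
  total <- sum(unlist(out[gp_compartments()])) + out$exited_cum
  expect_equal(total, out$entered_cum, tolerance = 1e-12)
})

test_that("steps conserve persons exactly", {
  set.seed(31)
  for (i in 1:20) {
    cfg <- random_config()
    st <- gp_state(
      t = runif(1, 0, 15), undecided = runif(1, 0, 30),
      P = runif(1, 0, 30), PI = runif(1, 0, 30), N = runif(1, 0, 30),
      NI = runif(1, 0, 30), NE = runif(1, 0, 30), NIN = runif(1, 0, 30),
      pending = runif(1, 0, 30), heat_active = runif(1) < 0.5
    )
    f <- compute_flows(st, cfg$params, cfg)
    out <- gp_step(st, cfg$params, cfg, f)
    total <- sum(unlist(out[gp_compartments()])) + out$exited_cum
    expect_equal(total, out$entered_cum, tolerance = 1e-10)
    expect_true(all(unlist(out[gp_compartments()]) >= 0))
  }
})

test_that("a non-positive step size is a domain error", {
  cfg <- gp_config()
  st <- gp_state(P = 1)
  f <- compute_flows(st, cfg$params, cfg)
  bad <- cfg
  bad$dt <- -0.1
  expect_error(gp_step(st, bad$params, bad, f), "dt")
})
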