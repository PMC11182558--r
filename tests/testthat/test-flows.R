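test_that("named flows match their rate laws", {
  cfg <- gp_config()
  pr <- cfg$params # lambda2 = 0.2, T_c = 2

  # emotional guidance converts interacting negatives at NI*lambda2/T_c
  f <- compute_flows(gp_state(NI = 10), pr, cfg)
  expect_equal(f$v5, 10 * 0.2 / 2)
  expect_equal(f$v4, 10 / pr$T_e)
  expect_equal(f$v9, 10 * 0.2 / pr$T_ef)

  # heat reduction de-escalates extremes at NE*lambda3/T_ef once active
  f <- compute_flows(gp_state(NE = 7, heat_active = TRUE), pr, cfg)
  expect_equal(f$v11, 7 * 0.4 / 7)

  # interaction entries scale with information uncertainty
  f <- compute_flows(gp_state(P = 12, N = 6), pr, cfg)
  expect_equal(f$v1, 12 * 0.5 / 3)
  expect_equal(f$v3, 6 * 0.5 / 1)

  # all-zero state carries no flow
  f <- compute_flows(gp_state(), pr, cfg)
  expect_true(all(as.numeric(f) == 0))
})

test_that("heat-reduction flows are latched on the NE threshold", {
  cfg <- gp_config(heat_threshold = 1)
  pr <- cfg$params
  # below threshold, never exceeded: v10 and v11 stay off
  f <- compute_flows(gp_state(NE = 0.5, NIN = 10), pr, cfg)
  expect_equal(f$v10, 0)
  expect_equal(f$v11, 0)
  # same occupancy but latch set: both act
  f <- compute_flows(gp_state(NE = 0.5, NIN = 10, heat_active = TRUE),
                     pr, cfg)
  expect_gt(f$v10, 0)
  expect_gt(f$v11, 0)
  # current NE above threshold activates without the latch
  f <- compute_flows(gp_state(NE = 2, NIN = 10), pr, cfg)
  expect_gt(f$v11, 0)
})

test_that("event coupling switches v7 and v10 off when absent", {
  cfg <- gp_config(gp_params(lambda4 = 0))
  st <- gp_state(PI = 20, NIN = 15, NE = 3, heat_active = TRUE)
  f <- compute_flows(st, cfg$params, cfg)
  expect_equal(f$v7, 0)
  expect_equal(f$v10, 0)
  # and with coupling present both are positive
  cfg2 <- gp_config(gp_params(lambda4 = 0.9))
  f2 <- compute_flows(st, cfg2$params, cfg2)
  expect_gt(f2$v7, 0)
  expect_gt(f2$v10, 0)
})

test_that("the escalation ratio is guarded and capped when NE is empty", {
  cfg <- gp_config(ratio_cap = 10)
  pr <- cfg$params
  st <- gp_state(PI = 10, NIN = 50, NE = 0, heat_active = TRUE)
  f <- compute_flows(st, pr, cfg)
  expect_true(all(is.finite(as.numeric(f))))
  # v7's ratio saturates at 1, v10's at ratio_cap
  expect_equal(f$v7, 10 * pr$lambda4 / (pr$T_c * pr$T_e))
  expect_equal(f$v10, 50 * pr$lambda4 / pr$T_e * 10)
})

test_that("flows from any valid state are non-negative and clamped", {
  set.seed(7)
  for (i in 1:30) {
    cfg <- random_config()
    st <- gp_state(
      t = runif(1, 0, 20), undecided = runif(1, 0, 50),
      P = runif(1, 0, 50), PI = runif(1, 0, 50), PIP = runif(1, 0, 50),
      N = runif(1, 0, 50), NI = runif(1, 0, 50), NE = runif(1, 0, 50),
      NIN = runif(1, 0, 50), heat_active = runif(1) < 0.5
    )
    f <- compute_flows(st, cfg$params, cfg)
    expect_true(all(as.numeric(f) >= 0))
    # per-stock outflow within one dt never exceeds the stock
    dt <- cfg$dt
    expect_lte((f$v1 + f$exit_P) * dt, st$P + 1e-12)
    expect_lte((f$v4 + f$v5 + f$v9 + f$exit_NI) * dt, st$NI + 1e-12)
    expect_lte((f$v6 + f$v7 + f$exit_PI_to_PIP) * dt, st$PI + 1e-12)
    expect_lte((f$v10 + f$exit_NIN) * dt, st$NIN + 1e-12)
    expect_lte((f$v11 + f$exit_NE) * dt, st$NE + 1e-12)
  }
})

test_that("v2 is the PI lifecycle flow and v8 is folded into v5", {
  cfg <- gp_config()
  f <- compute_flows(gp_state(t = 10, PI = 10), cfg$params, cfg)
  expect_equal(f$v2, f$exit_PI_to_PIP)
  expect_equal(f$v2, 10 * 10 / cfg$exit_scale_days)
  expect_equal(f$v8, 0)
})
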