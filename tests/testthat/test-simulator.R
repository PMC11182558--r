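test_that("an empty system stays empty", {
  traj <- run_gp(gp_config(gp_params(S0 = 0), horizon = 10, dt = 0.1))
  for (cc in gp_compartments()) expect_true(all(traj[[cc]] == 0))
  expect_true(all(traj$entered_cum == 0))
})

test_that("without information uncertainty no interaction states form", {
  traj <- run_gp(gp_config(gp_params(lambda6 = 0), horizon = 40, dt = 0.1))
  for (cc in c("PI", "NI", "NIN", "NE")) {
    expect_true(all(traj[[cc]] == 0), label = cc)
  }
  # entrants still split into P and N and eventually exit
  expect_gt(max(traj$P), 0)
  expect_gt(max(traj$N), 0)
})

test_that("trajectories start empty and conserve persons throughout", {
  traj <- run_gp(baseline_scenario())
  first <- traj[1, ]
  expect_equal(first$t, 0)
  for (cc in setdiff(gp_compartments(), "undecided")) {
    expect_equal(first[[cc]], 0)
  }
  expect_equal(first$undecided, first$entered_cum)
  expect_lte(max_imbalance(traj), 1e-8 * max(traj$entered_cum))
})

test_that("stocks stay non-negative and conservative for random configs", {
  set.seed(101)
  for (i in 1:8) {
    cfg <- random_config(mode = sample(c("meanfield", "stochastic"), 1))
    traj <- run_gp(cfg)
    stocks <- as.matrix(traj[, gp_compartments()])
    expect_true(all(stocks >= 0))
    expect_true(all(is.finite(stocks)))
    expect_lte(max_imbalance(traj), 1e-8 * max(traj$entered_cum, 1))
  }
})

test_that("identical config and seed reproduce the trajectory exactly", {
  cfg <- gp_config(mode = "stochastic", seed = 123, horizon = 15, dt = 0.1)
  expect_identical(as.data.frame(run_gp(cfg)), as.data.frame(run_gp(cfg)))
})

test_that("the baseline extreme-opinion curve is unimodal and recedes", {
  traj <- run_gp(baseline_scenario())
  ne <- traj$NE
  expect_equal(ne[1], 0)
  i_pk <- which.max(ne)
  expect_gt(i_pk, 1)
  expect_lt(i_pk, length(ne))
  # strictly one rise and one fall (tolerate floating-point dust)
  d <- diff(ne)
  sign_changes <- sum(diff(sign(d[abs(d) > 1e-12])) != 0)
  expect_lte(sign_changes, 1)
  # basic recession by the end of the horizon
  expect_lt(ne[length(ne)], 0.05 * max(ne))
})

test_that("early-opinion peaks precede interaction peaks precede the NE peak", {
  traj <- run_gp(baseline_scenario())
  pk <- function(cc) traj$t[which.max(traj[[cc]])]
  expect_lt(max(pk("P"), pk("N")), min(pk("PI"), pk("NI")))
  expect_lt(max(pk("PI"), pk("NI")), pk("NE"))
})

test_that("daily recording keeps one row per day", {
  cfg <- gp_config(horizon = 30, dt = 0.05)
  traj <- run_gp(cfg, record = "daily")
  expect_equal(nrow(traj), 31)
  expect_equal(traj$t, as.numeric(0:30))
  # default cadence records every step
  expect_equal(nrow(run_gp(cfg)), 30 / 0.05 + 1)
})

test_that("ensembles are reproducible and degenerate correctly", {
  cfg <- gp_config(mode = "stochastic", seed = 7, horizon = 10, dt = 0.1)
  e1 <- run_ensemble(cfg, 3)
  e2 <- run_ensemble(cfg, 3)
  expect_identical(map(e1, as.data.frame), map(e2, as.data.frame))
  expect_identical(attr(e1, "child_seeds"), attr(e2, "child_seeds"))

  # replicate 1 equals a single run with the derived child seed
  cfg1 <- cfg
  cfg1$seed <- attr(e1, "child_seeds")[1]
  expect_identical(as.data.frame(e1[[1]]),
                   as.data.frame(run_gp(cfg1, record = "daily")))

  # mean-field "ensembles" warn and collapse to a single run
  mf <- gp_config(horizon = 10, dt = 0.1)
  expect_warning(e <- run_ensemble(mf, 5), "identical")
  expect_length(e, 1)
})

test_that("the ensemble mean averages pointwise", {
  cfg <- gp_config(mode = "stochastic", seed = 5, horizon = 5, dt = 0.1)
  ens <- run_ensemble(cfg, 4)
  m <- ensemble_mean(ens)
  expect_equal(m$NE, rowMeans(vapply(ens, function(tr) tr$NE,
                                     numeric(nrow(m)))))
})
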