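test_that("no selection pressure means no evolution", {
  # flat fitness surface (huge width) and a quiet environment
  cfg <- run_config(
    env = env_config(cue_ramp_slopes = c(0, 0),
                     noise_cov = diag(1e-6, 4), n_gen = 8),
    fit = fitness_config(W_max = 4, omega2 = 1e12),
    n = 30, methods = c("robertson", "grad", "breeder"), seed = 2
  )
  traj <- run_generation_loop(cfg)
  for (m in cfg$methods) {
    tm <- dplyr::filter(traj, method == m)
    expect_lt(max(abs(tm$abar1 - tm$abar1[1])), 1e-9)
    expect_lt(max(abs(tm$bbar11 - tm$bbar11[1])), 1e-9)
  }
})

test_that("Robertson/BLUP and GRAD trajectories are identical for unrelated populations", {
  cfg <- run_config(env = env_config(n_gen = 25), n = 50,
                    methods = c("robertson", "grad"), seed = 3)
  traj <- run_generation_loop(cfg)
  expect_lt(method_gap(traj, "robertson", "grad"), 1e-8)
})

test_that("Robertson/BLUP and GRAD diverge under genetic relatedness", {
  cfg <- run_config(rel = "band", n = 100,
                    methods = c("robertson", "grad"), seed = 4)
  traj <- run_generation_loop(cfg)
  expect_gt(method_gap(traj, "robertson", "grad"), 1e-3)
})

test_that("mean traits track the moving fitness peak with a lag", {
  cfg <- run_config(methods = "robertson", seed = 5)
  traj <- run_generation_loop(cfg)
  last <- dplyr::filter(traj, t == max(t))
  # deterministic peak position at the end of the ramp
  theta1_mean <- -2 * 0.05 * (60 - 10)
  # the evolving population ends far closer to the peak than a
  # non-evolving control frozen at the initial mean parameters
  u1_mean_end <- 0.05 * (60 - 10)
  control_ybar1 <- 0 + (-0.5) * u1_mean_end
  expect_lt(abs(last$ybar1 - theta1_mean), abs(control_ybar1 - theta1_mean))
  # and moves in the peak's direction from the start
  expect_lt(last$ybar1, -1)
})

test_that("shared-seed trajectories are reproducible and method divergence is rule-driven", {
  cfg <- run_config(env = env_config(n_gen = 10), n = 40,
                    methods = c("robertson", "breeder"), seed = 6)
  t1 <- run_generation_loop(cfg)
  t2 <- run_generation_loop(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # the environment snapshot is shared across methods within a run
  wide <- tidyr::pivot_wider(t1[c("t", "method", "u1")],
                             names_from = "method", values_from = "u1")
  expect_identical(wide$robertson, wide$breeder)
})

test_that("halving the offspring fraction halves each increment and slows the response", {
  cfg <- run_config(rel = "band", methods = "robertson", seed = 7)
  res <- overlap_experiment(cfg, ft_values = c(1, 0.5))
  traj <- res$trajectories
  t1 <- dplyr::filter(traj, ft == 1)
  th <- dplyr::filter(traj, ft == 0.5)
  # first-generation increments (identical state, shared draws) halve exactly
  d1 <- t1$abar1[t1$t == 2] - t1$abar1[t1$t == 1]
  dh <- th$abar1[th$t == 2] - th$abar1[th$t == 1]
  expect_equal(dh, d1 / 2, tolerance = 1e-12)
  # slower response: less total movement of the mean intercept
  expect_lt(abs(th$abar1[th$t == 60] - th$abar1[th$t == 1]),
            abs(t1$abar1[t1$t == 60] - t1$abar1[t1$t == 1]))
  # lower time-averaged fitness over the ramp period
  s <- res$summary
  expect_lt(s$mean_W[s$ft == 0.5], s$mean_W[s$ft == 1])
  # ft = 1 reproduces the plain generation loop exactly
  plain <- run_generation_loop(cfg, seed = 7)
  expect_equal(t1$abar1, plain$abar1)
})

test_that("stationary-environment drift scales with population size and vanishes without noise", {
  base_env <- env_config(cue_ramp_slopes = c(0, 0))
  cfg100 <- run_config(env = base_env, n = 100, methods = "robertson",
                       seed = 8)
  d100 <- drift_experiment(cfg100, reps = 100)
  expect_lt(abs(d100$mean_change), 0.1)
  expect_gt(d100$sd_change, 0.03)
  expect_lt(d100$sd_change, 0.30)
  cfg2 <- run_config(env = base_env, n = 2, methods = "robertson", seed = 8)
  d2 <- drift_experiment(cfg2, reps = 120)
  expect_gt(d2$sd_change, d100$sd_change)
  # no environmental noise and a flat fitness surface: no drift at all
  cfg0 <- run_config(
    env = env_config(cue_ramp_slopes = c(0, 0), noise_cov = diag(1e-12, 4),
                     n_gen = 20),
    fit = fitness_config(omega2 = 1e12), n = 20,
    methods = "robertson", seed = 9
  )
  d0 <- drift_experiment(cfg0, reps = 5)
  expect_lt(d0$sd_change, 1e-6)
})

test_that("environmental drift diagnostic matches the OLS closed form and scales with noise", {
  cfg <- run_config(env = env_config(cue_ramp_slopes = c(0, 0)), seed = 10)
  res <- env_drift_diagnostic(cfg, reps = 100)
  tt <- 1:60
  analytic <- 59 * sqrt(0.5 / sum((tt - mean(tt))^2))
  mc_se <- analytic / sqrt(2 * 99)
  expect_lt(abs(res$sd_change - analytic), 3 * mc_se)
  expect_lt(abs(res$mean_change), 3 * analytic / sqrt(100))
  # quadrupling the cue variance doubles the spread (up to Monte Carlo error)
  S4 <- default_noise_cov()
  S4[1, ] <- S4[1, ] * 2; S4[, 1] <- S4[, 1] * 2
  cfg4 <- run_config(env = env_config(cue_ramp_slopes = c(0, 0),
                                      noise_cov = S4), seed = 10)
  res4 <- env_drift_diagnostic(cfg4, reps = 100)
  expect_lt(abs(res4$sd_change / res$sd_change - 2), 0.6)
})

test_that("method gap summaries", {
  cfg <- run_config(env = env_config(n_gen = 6), n = 20,
                    methods = c("robertson", "grad"), seed = 11)
  traj <- run_generation_loop(cfg)
  a <- dplyr::filter(traj, method == "robertson")
  expect_equal(method_gap_summary(a, a), 0)
  expect_error(method_gap_summary(a, a[1:3, ]), "length")
  expect_error(method_gap(traj, "robertson", "nope"), "not found")
})

test_that("trajectory plots build without error", {
  cfg <- run_config(env = env_config(n_gen = 5), n = 20,
                    methods = "robertson", seed = 12)
  traj <- run_generation_loop(cfg)
  expect_s3_class(ggplot2::autoplot(traj), "ggplot")
  env <- make_env_trajectory(env_config(n_gen = 5), seed = 1)
  expect_s3_class(ggplot2::autoplot(env), "ggplot")
})
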