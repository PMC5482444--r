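test_that("the agent time step is min(T, L/v, tau/20) and the stop rule 50T", {
  cfg <- make_sim_config(1e4, 20, 33)
  expect_equal(cfg$dt_B, 1.65)
  expect_equal(cfg$stop_attractant, 50 * 1e4)
  expect_equal(make_sim_config(1e4, 100, 0.020)$dt_B, 0.001)
  expect_equal(make_sim_config(0.1, 100, 100)$dt_B, 0.1)
})

test_that("a never-tumbling agent runs ballistically with periodic wrap", {
  p <- null_response(100, 20)
  env <- constant_environment(1)
  cfg <- make_sim_config(100, 20, p$tau)
  set.seed(2)
  ag <- init_agent(env, p, cfg)
  x0 <- ag$x
  dir <- if (ag$mode == "run_right") 1 else -1
  for (k in 1:25) ag <- step_agent(ag, env, p, cfg)
  expect_equal(ag$x, (x0 + dir * 25 * cfg$v * cfg$dt_B) %% cfg$ell)
  expect_equal(ag$accumulated, 25 * cfg$dt_B)
  expect_true(ag$x >= 0 && ag$x < cfg$ell)
})

test_that("tumbling agents hold position and exit with rate beta", {
  # beta -> infinity: leaves the tumble in one step
  p_fast <- response_params("inverted", alpha0 = 0, beta = 1e9, A = 1e-9,
                            tau = 1)
  env <- constant_environment(0)
  cfg <- make_sim_config(100, 20, p_fast$tau)
  ag <- init_agent(env, p_fast, cfg)
  ag$mode <- "tumble"
  ag <- step_agent(ag, env, p_fast, cfg)
  expect_true(ag$mode %in% c("run_left", "run_right"))

  # beta ~ 0: stays tumbling, position frozen
  p_slow <- response_params("inverted", alpha0 = 0, beta = 1e-12, A = 1e-9,
                            tau = 1)
  ag <- init_agent(env, p_slow, cfg)
  ag$mode <- "tumble"
  x0 <- ag$x
  for (k in 1:50) ag <- step_agent(ag, env, p_slow, cfg)
  expect_equal(ag$mode, "tumble")
  expect_equal(ag$x, x0)
})

test_that("post-tumble run directions are balanced", {
  p <- response_params("inverted", alpha0 = 4, beta = 4, A = 1e-12, tau = 1)
  env <- constant_environment(0)
  cfg <- make_sim_config(100, 100, p$tau)
  set.seed(11)
  ag <- init_agent(env, p, cfg)
  dirs <- integer(0)
  prev <- ag$mode
  for (k in 1:6000) {
    ag <- step_agent(ag, env, p, cfg)
    if (prev == "tumble" && ag$mode != "tumble")
      dirs <- c(dirs, ag$mode == "run_right")
    prev <- ag$mode
  }
  expect_gt(length(dirs), 200)
  expect_equal(mean(dirs), 0.5, tolerance = 3 / sqrt(length(dirs)))
})

test_that("time to threshold in a constant environment is exact and linear", {
  p <- null_response(100, 20)
  cfg <- make_sim_config(100, 20, p$tau)
  set.seed(1)
  s1 <- simulate_agent(p, constant_environment(1), cfg)
  expect_false(s1$truncated)
  expect_lte(abs(s1$D - 50 * 100), cfg$dt_B + 1e-9)
  s2 <- simulate_agent(p, constant_environment(2), cfg)
  expect_lte(abs(s2$D - 25 * 100), cfg$dt_B + 1e-9)
})

test_that("run lengths under constant rate are exponential in the fine-step limit", {
  alpha <- 2
  p <- response_params("inverted", alpha0 = alpha, beta = 50, A = 1e-12,
                       tau = 20 / (100 * alpha)) # dt_B = tau/20 = 1/(100 alpha)
  env <- constant_environment(0)
  cfg <- make_sim_config(1e4, 1e4, p$tau, ell = 100)
  expect_equal(cfg$dt_B, 1 / (100 * alpha))
  set.seed(21)
  ag <- init_agent(env, p, cfg)
  runs <- numeric(0)
  cur <- 0
  for (k in 1:4e4) {
    ag <- step_agent(ag, env, p, cfg)
    if (ag$mode == "tumble") {
      if (cur > 0) runs <- c(runs, cur)
      cur <- 0
    } else cur <- cur + cfg$dt_B
  }
  expect_gt(length(runs), 100)
  expect_equal(mean(runs), 1 / alpha, tolerance = 0.2)
  # geometric run lengths: P(run > t) ~ exp(-alpha t)
  expect_equal(mean(runs > 1 / alpha), exp(-1), tolerance = 0.12)
})

test_that("compiled simulator reproduces the closed-form step response", {
  p <- demo_speculator(beta = 2)
  env <- step_environment(1, 50, 350)
  cfg <- make_sim_config(1e4, 1e4, p$tau, ell = 100,
                         stop_attractant = Inf, t_max = 500)
  set.seed(3)
  sim <- simulate_agent(p, env, cfg, record = TRUE, record_every = cfg$dt_B)
  tr <- sim$trajectory
  expected <- step_response_rate(p, 1, 50, 350, tr$t)
  expect_lt(max(abs(tr$alpha - expected) / pmax(expected, 1e-12)), 1e-9)
  # recorded positions stay in the periodic world
  expect_true(all(tr$x >= 0 & tr$x < 100))
  # accumulated attractant is non-decreasing
  expect_true(all(diff(tr$accumulated) >= 0))
})

test_that("an always-running agent samples the field's spatial mean", {
  # tau sized so the step resolves the correlation length (dt_B = 2)
  p <- response_params("null", alpha0 = 0, beta = 1, tau = 40)
  fp <- field_params(100, 20)
  cfg <- make_sim_config(100, 20, p$tau)
  set.seed(14)
  cbar <- vapply(1:30, function(i) {
    s <- simulate_agent(p, stochastic_environment(fp, i), cfg)
    s$accumulated / s$D
  }, numeric(1))
  expect_equal(mean(cbar), 1 / sqrt(2 * pi), tolerance = 0.05)
})

test_that("step-response direction differs qualitatively by strategy", {
  # with optimized-style parameters: adaptive spikes on removal; inverted
  # and speculator rise on addition
  pa <- response_params("adaptive", alpha0 = 0.0084, beta = 54, B = 1500,
                        tau = 0.020)
  pi_ <- response_params("inverted", alpha0 = 0.0063, beta = 1, A = 4.4,
                         tau = 5.0)
  ps <- response_params("speculator", alpha0 = 0.0089, beta = 0.056, A = 74,
                        B = -67, tau = 33)
  t_on <- 50; t_off <- 350
  t <- seq(0, 700, by = 1e-3)
  a_ad <- step_response_rate(pa, 1, t_on, t_off, t)
  expect_gt(max(a_ad[t >= t_off]), 100)       # spike at removal
  expect_equal(a_ad[t == 300], pa$alpha0)     # readapted before removal
  a_inv <- step_response_rate(pi_, 1, t_on, t_off, seq(0, 700, by = 0.5))
  expect_equal(max(a_inv), pi_$alpha0 + 4.4, tolerance = 1e-3)
  a_sp <- step_response_rate(ps, 1, t_on, t_off, c(49, 120))
  expect_gt(a_sp[2], a_sp[1]) # rises on addition
})
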