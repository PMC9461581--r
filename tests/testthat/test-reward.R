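# Reward accounting, reward rate and strategy optimisation.

test_that("total food consumed follows the telescoping depletion form", {
  env <- ref_env()
  # a lone forager eventually consumes the whole patch (rho * tau)
  expect_equal(total_food_consumed(200, env, n = 1), env$rho * env$tau,
               tolerance = 1e-10)
  # instantaneous departure consumes nothing
  expect_equal(total_food_consumed(c(0, 0), env), 0)
  # simultaneous two-agent departure: rho tau (1 - e^(-2T/tau))
  T <- 3
  expect_equal(total_food_consumed(c(T, T), env),
               env$rho * env$tau * (1 - exp(-2 * T / env$tau)))
  expect_error(total_food_consumed(c(3, 1), env), "sorted")
})

test_that("telescoping form equals direct integration of the depletion dynamics", {
  env <- patch_env(rho = 3, tau = 4, alpha = 1, travel_time = 2)
  set.seed(77)
  worst <- 0
  for (k in 1:100) {
    n <- sample(2:4, 1)
    ts <- sort(runif(n, 0, 12))
    closed <- total_food_consumed(ts, env, n)
    # oracle: adaptive quadrature of N(t) * rho * exp(-Lambda(t)),
    # segment by segment between decision times (smooth integrand)
    bounds <- unique(c(0, ts))
    quad <- sum(vapply(seq_len(length(bounds) - 1), function(i)
      stats::integrate(function(s)
        counting_function(ts, s, n) * env$rho *
          exp(-depletion_exponent(ts, s, env$tau, n)),
        bounds[i], bounds[i + 1], rel.tol = 1e-10)$value, numeric(1)))
    worst <- max(worst, abs(closed - quad) / max(quad, 1e-12))
    expect_lte(closed, env$rho * env$tau + 1e-9)
  }
  expect_lt(worst, 1e-6)
})

test_that("reward rate is net energy per unit time", {
  env <- ref_env()
  # break-even
  expect_equal(reward_rate(env$alpha * (env$travel_time + 3), 3, env), 0)
  # pure cost
  expect_equal(reward_rate(0, 3, env), -env$alpha)
  # linear in the reward at fixed time
  r <- 4; tm <- 3
  expect_equal(reward_rate(2 * r, tm, env) - reward_rate(r, tm, env),
               r / (env$travel_time + tm))
  expect_error(reward_rate(1, -1, env), "mean_group_time")
  env0 <- patch_env(2, 5, 1, travel_time = 0)
  expect_error(reward_rate(1, 0, env0), "positive")
})

test_that("strategy evaluation is reproducible and label-invariant", {
  env <- ref_env()
  s <- sim_settings(n_trials = 400, seed = 31)
  e1 <- evaluate_strategy(two_agent("diffusive", -1, kappa = 0.5), s)
  e2 <- evaluate_strategy(two_agent("diffusive", -1, kappa = 0.5), s)
  expect_identical(e1$rr, e2$rr)
  # kappa = 0 coupled model equals mode = none at the same seed
  e3 <- evaluate_strategy(two_agent("diffusive", -1, kappa = 0), s)
  e4 <- evaluate_strategy(two_agent("none", -1), s)
  expect_identical(e3$rr, e4$rr)
  # permuting agent labels leaves RR unchanged (asymmetric strategies)
  m_ab <- group_model("diffusive", env,
                      agents = list(agent_strategy(-1, 0.3),
                                    agent_strategy(-2, 1)), noise_scale = 1)
  m_ba <- group_model("diffusive", env,
                      agents = list(agent_strategy(-2, 1),
                                    agent_strategy(-1, 0.3)), noise_scale = 1)
  ea <- evaluate_strategy(m_ab, s)
  eb <- evaluate_strategy(m_ba, s)
  expect_equal(ea$rr, eb$rr, tolerance = 6 * (ea$se + eb$se))
})

test_that("standard errors shrink like one over root n", {
  m <- two_agent("none", -1)
  e_small <- evaluate_strategy(m, sim_settings(n_trials = 200, seed = 3))
  e_big <- evaluate_strategy(m, sim_settings(n_trials = 3200, seed = 3))
  expect_equal(e_small$se / e_big$se, 4, tolerance = 0.35)
})

test_that("symmetric sweep extracts a smoothed optimal-threshold curve", {
  env <- ref_env()
  s <- sim_settings(n_trials = 150, seed = 41)
  # one-cell sweep equals a direct evaluation
  sw1 <- sweep_symmetric("diffusive", env, theta_grid = -1, kappa_grid = 0.5,
                         B = 1, settings = s)
  ev <- evaluate_strategy(two_agent("diffusive", -1, kappa = 0.5), s)
  expect_equal(sw1$surface$rr, ev$rr)
  expect_equal(sw1$optimal_theta$theta_opt, -1)
  # sliding-window smoothing leaves a constant curve unchanged
  expect_equal(socforage:::smooth_window3(rep(2.5, 7)), rep(2.5, 7))
  # infinite-coupling column comes from the limiting model
  sw2 <- sweep_symmetric("pulsatile", env, theta_grid = c(-1.5, -1),
                         kappa_grid = 1, B = 1, settings = s,
                         include_infinite = TRUE)
  expect_true(Inf %in% sw2$surface$kappa)
  expect_true(all(is.finite(sw2$surface$rr)))
})

test_that("partner optimisation recovers consistent optima and breaks ties", {
  env <- ref_env()
  s <- sim_settings(n_trials = 250, seed = 51)
  # degenerate one-cell free grid returns that cell
  out <- optimize_partner(agent_strategy(-1, 0.5), theta_grid = -1.2,
                          kappa_grid = 0.7, mode = "diffusive", env = env,
                          B = 1, settings = s)
  expect_equal(out$theta2, -1.2)
  expect_equal(out$kappa2, 0.7)
  expect_equal(nrow(out$surface), 1)
})
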