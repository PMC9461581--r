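# Domain types and the shared drift/coupling primitives.

test_that("constructors enforce model invariants", {
  expect_error(patch_env(rho = 1, tau = 5, alpha = 1), "rho > alpha")
  expect_error(patch_env(rho = 2, tau = 0, alpha = 1), "tau")
  expect_error(patch_env(rho = 2, tau = 5, alpha = 1, travel_time = -1),
               "travel_time")
  expect_error(agent_strategy(theta = 0.5), "negative")
  expect_error(agent_strategy(theta = -1, kappa = -0.1), "kappa")
  env <- ref_env()
  expect_error(group_model("none", env, theta = -1, noise_scale = 0),
               "noise_scale")
  expect_error(group_model("none", env, agents = list()), "agent")
  expect_error(sim_settings(dt = 0), "dt")
})

test_that("counting function is the right-continuous active-forager count", {
  expect_identical(counting_function(numeric(0), 3.7, n = 2), 2)
  expect_identical(counting_function(1.0, 1.5, n = 2), 1)
  expect_identical(counting_function(c(1.0, 2.0), 5.0, n = 2), 0)
  # right-continuity: at exactly T_j the post-decision count
  expect_identical(counting_function(1.0, 1.0, n = 2), 1)
  expect_error(counting_function(1.0, -0.1, n = 2), "non-negative")
  # piecewise constant and non-increasing on a fine grid
  tt <- seq(0, 6, by = 0.01)
  nn <- counting_function(c(1, 2.5, 4), tt, n = 3)
  expect_true(all(diff(nn) <= 0))
  expect_true(all(nn %in% 0:3))
})

test_that("depletion exponent integrates the counting function", {
  tau <- 5
  expect_equal(depletion_exponent(numeric(0), 3, tau, n = 1), 3 / tau)
  expect_equal(depletion_exponent(numeric(0), 3, tau, n = 2), 6 / tau)
  # after the first of two decides at T1, slope drops to 1/tau
  T1 <- 2
  t <- 3.5
  expect_equal(depletion_exponent(T1, t, tau, n = 2),
               (2 * T1 + (t - T1)) / tau)
  # continuity across the decision time and Lambda(0) = 0
  expect_equal(depletion_exponent(T1, T1, tau, n = 2), 2 * T1 / tau)
  expect_equal(depletion_exponent(c(1, 2), 0, tau, n = 2), 0)
  # oracle: adaptive quadrature of the counting function, segment by
  # segment (the integrand is constant between decision times)
  ev <- c(1, 2.5)
  bounds <- c(0, ev, 8)
  lam_quad <- sum(vapply(seq_len(length(bounds) - 1), function(i)
    stats::integrate(function(s) counting_function(ev, s, n = 2),
                     bounds[i], bounds[i + 1])$value, numeric(1))) / tau
  expect_equal(depletion_exponent(ev, 8, tau, n = 2), lam_quad,
               tolerance = 1e-8)
})

test_that("drift follows the continuous depleting resource", {
  env <- ref_env()
  expect_equal(patch_drift(numeric(0), 0, env, n = 3), env$rho - env$alpha)
  # single forager at t = 5 tau: rho e^-5 - alpha < 0 (eventual crossing)
  d <- patch_drift(numeric(0), 5 * env$tau, env, n = 1)
  expect_equal(d, 2 * exp(-5) - 1)
  expect_lt(d, 0)
  # two active foragers look like one at doubled time
  t <- 1.7
  expect_equal(patch_drift(numeric(0), t, env, n = 2),
               patch_drift(numeric(0), 2 * t, env, n = 1))
  # no density jump at a decision time
  T1 <- 2
  eps <- 1e-9
  expect_equal(patch_drift(T1, T1 + eps, env, n = 2),
               patch_drift(numeric(0), T1, env, n = 2), tolerance = 1e-6)
})

test_that("diffusive coupling pulls toward decided neighbours", {
  st <- function(theta, kappa) agent_strategy(theta, kappa)
  # equal distances-to-threshold: symmetric cancellation
  out <- coupling_drift_diffusive(c(-1 + 0.7, -2 + 0.7),
                                  list(st(-1, 2), st(-2, 3)))
  expect_equal(out, c(0, 0))
  # decided neighbour at threshold: increment is -kappa * distance
  d <- 0.8
  out2 <- coupling_drift_diffusive(c(-1 + d, -2), list(st(-1, 1.5), st(-2, 1)),
                                   active = c(TRUE, FALSE))
  expect_equal(out2[1], -1.5 * d)
  expect_equal(out2[2], 0)
  # three agents: matches brute-force pairwise summation
  states <- c(0.3, -0.4, 1.1)
  strat <- list(st(-1, 0.7), st(-1.5, 1.2), st(-0.5, 0.4))
  gaps <- states - c(-1, -1.5, -0.5)
  brute <- vapply(1:3, function(i)
    strat[[i]]$kappa * sum(gaps[-i] - gaps[i]), numeric(1))
  expect_equal(coupling_drift_diffusive(states, strat), brute)
})

test_that("pulse rule cascades and terminates", {
  st <- function(theta, kappa) agent_strategy(theta, kappa)
  # zero pulse: no state change, no cascade
  out <- apply_pulse(c(-1, 0.2), list(st(-1, 0), st(-1, 0)), 1)
  expect_equal(out$states[2], 0.2)
  expect_length(out$cascade, 0)
  # pulse spanning the remaining distance triggers the neighbour
  out2 <- apply_pulse(c(-1, -0.5), list(st(-1, 1), st(-1, 1)), 1)
  expect_equal(out2$cascade, 2L)
  expect_equal(out2$states, c(-1, -1))
  # chain: 1 triggers 2 (but not 3), 2's pulse then triggers 3
  # brute-force recursion oracle built by hand:
  #   x2 = -0.6, kappa2 = 0.5 -> -1.1 <= -1 (crosses)
  #   x3 = -0.2, kappa3 = 0.45 -> -0.65 (survives 1's pulse),
  #        second pulse -> -1.1 <= -1 (crosses)
  out3 <- apply_pulse(c(-1, -0.6, -0.2),
                      list(st(-1, 1), st(-1, 0.5), st(-1, 0.45)), 1)
  expect_equal(out3$cascade, c(2L, 3L))
  expect_equal(out3$states, c(-1, -1, -1))
  # idempotence guard: an already-decided decider is a usage error
  expect_error(apply_pulse(c(-1, 0), list(st(-1, 1), st(-1, 1)), 1,
                           decided = c(TRUE, FALSE)), "already decided")
})

test_that("departure records order times and set the group time", {
  r <- departure_record(c(3.2, 1.5, 2.0))
  expect_equal(r$ordered_times, c(1.5, 2.0, 3.2))
  expect_equal(r$group_time, 3.2)
  expect_equal(r$decider_order, c(2L, 3L, 1L))
})
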