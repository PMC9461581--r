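# Fokker-Planck solver and pair-likelihood backends.

test_that("solver reproduces the inverse-Gaussian density and converges", {
  D <- 0.5
  theta <- -1
  mu <- 1
  sol <- solve_fp_1d(function(t) -mu, D, theta, c(0, 10),
                     grid_spec(x_max = 4, nx = 250, dt_pde = 0.01))
  ig <- inverse_gaussian_fpt(sol$fpt$time, a = abs(theta), mu = mu, D = D)
  err <- max(abs(sol$fpt$density - ig))
  expect_lt(err, 0.025) # peak density is ~1.07
  # refinement shrinks the error
  sol2 <- solve_fp_1d(function(t) -mu, D, theta, c(0, 10),
                      grid_spec(x_max = 4, nx = 500, dt_pde = 0.005))
  ig2 <- inverse_gaussian_fpt(sol2$fpt$time, abs(theta), mu, D)
  expect_lt(max(abs(sol2$fpt$density - ig2)), err / 1.5)
  # mass balance: interior + absorbed accounted throughout
  S_from_f <- 1 - cumsum(sol$fpt$density) * 0.01
  expect_lt(max(abs(S_from_f - sol$fpt$survival)), 1e-8)
})

test_that("pure diffusion far from the boundary stays Gaussian", {
  D <- 0.4
  sol <- solve_fp_1d(function(t) 0, D, theta = -12, c(0, 1),
                     grid_spec(x_max = 12, nx = 480, dt_pde = 0.002))
  x <- seq(-12, 12, length.out = 480 + 1)[-1] # node coordinates
  gauss <- exp(-x^2 / (4 * D)) / sqrt(4 * pi * D)
  expect_lt(max(abs(sol$p_final - gauss)), 0.01)
  expect_gt(tail(sol$fpt$survival, 1), 0.999999)
})

test_that("no-coupling pair density normalises and identifies theta", {
  env <- ref_env()
  tg <- seq(0.125, 25, by = 0.25)
  g2 <- expand.grid(t1 = tg, t2 = tg)
  g2 <- g2[g2$t2 >= g2$t1, ]
  ll <- pair_loglik_none(g2$t1, g2$t2, theta = -1, B = 1, env)
  w <- ifelse(g2$t2 - g2$t1 < 1e-9, 0.5, 1)
  expect_equal(sum(exp(ll) * w) * 0.25^2, 1, tolerance = 0.06)
  # only ordered times enter: label exchange is built in
  expect_error(pair_loglik_none(2, 1, -1, 1, env), "ordered")
  # likelihood over a theta grid peaks at the generating theta
  d <- simulate_dataset(two_agent("none", -1.5),
                        sim_settings(dt = 0.01, t_max = 120, n_trials = 300,
                                     seed = 21))
  p <- departure_pairs(d)
  thg <- seq(-3, -0.5, by = 0.25)
  lls <- vapply(thg, function(th)
    sum(pair_loglik_none(p$t1, p$t2, th, 1, env)), numeric(1))
  expect_equal(thg[which.max(lls)], -1.5, tolerance = 0.26)
})

test_that("pulsatile likelihood handles the simultaneity atom", {
  env <- ref_env()
  d <- simulate_dataset(two_agent("none", -1),
                        sim_settings(dt = 0.01, t_max = 120, n_trials = 100,
                                     seed = 22))
  p <- departure_pairs(d)
  # kappa = 0 reduces exactly to the no-coupling density
  expect_equal(pair_loglik_pulsatile(p$t1, p$t2, -1, 0, 1, env),
               pair_loglik_none(p$t1, p$t2, -1, 1, env))
  # conservation at fixed t1: atom + continuous mass = first-decider margin
  # 2 f(t1) S(t1), computed against the no-shift propagation oracle
  t1 <- 3
  t2g <- seq(t1 + 0.05, 40, by = 0.1)
  kappa <- 1.2
  ll_cont <- pair_loglik_pulsatile(rep(t1, length(t2g)), t2g, -1, kappa, 1,
                                   env, simultaneous = rep(FALSE, length(t2g)))
  ll_atom <- pair_loglik_pulsatile(t1, t1, -1, kappa, 1, env,
                                   simultaneous = TRUE)
  total <- sum(exp(ll_cont)) * 0.1 + exp(ll_atom)
  ll_nc <- pair_loglik_none(rep(t1, length(t2g)), t2g, -1, 1, env)
  total_nc <- sum(exp(ll_nc)) * 0.1
  expect_equal(total, total_nc, tolerance = 0.04)
  # a pulse spanning the attainable range sends (almost) all mass to the atom
  ll_cont_big <- pair_loglik_pulsatile(rep(t1, length(t2g)), t2g, -1, 50, 1,
                                       env,
                                       simultaneous = rep(FALSE, length(t2g)))
  ll_atom_big <- pair_loglik_pulsatile(t1, t1, -1, 50, 1, env,
                                       simultaneous = TRUE)
  expect_gt(exp(ll_atom_big) / (sum(exp(ll_cont_big)) * 0.1 + exp(ll_atom_big)),
            0.999)
  expect_equal(exp(ll_atom_big), total_nc, tolerance = 0.04)
  expect_error(pair_loglik_pulsatile(1, 2, -1, -0.5, 1, env), "kappa")
})

test_that("diffusive simulation likelihood is seeded and consistent", {
  env <- ref_env()
  d <- simulate_dataset(two_agent("none", -1),
                        sim_settings(dt = 0.01, t_max = 120, n_trials = 150,
                                     seed = 23))
  p <- departure_pairs(d)
  ll1 <- pair_loglik_diffusive(p$t1, p$t2, -1, 0.5, 1, env)
  ll2 <- pair_loglik_diffusive(p$t1, p$t2, -1, 0.5, 1, env)
  expect_identical(ll1, ll2) # deterministic given the likelihood seed
  # kappa = 0 agrees with the exact no-coupling backend up to kernel bias
  lld <- pair_loglik_diffusive(p$t1, p$t2, -1, 0, 1, env,
                               control = likelihood_control(sim_n = 4000))
  lln <- pair_loglik_none(p$t1, p$t2, -1, 1, env)
  expect_lt(mean(abs(lld - lln)), 0.5)
  expect_gt(cor(lld, lln), 0.85)
  # large kappa concentrates mass near the diagonal: near-simultaneous
  # pairs gain density relative to well-separated ones
  near <- pair_loglik_diffusive(3, 3.05, -1, 40, 1, env)
  far <- pair_loglik_diffusive(3, 6, -1, 40, 1, env)
  expect_gt(near, far)
  # likelihood surface over theta peaks near the generating value
  dd <- simulate_dataset(two_agent("diffusive", -1.5, kappa = 1),
                         sim_settings(dt = 0.01, t_max = 120, n_trials = 300,
                                      seed = 24))
  pd <- departure_pairs(dd)
  thg <- seq(-3, -0.5, by = 0.25)
  lls <- vapply(thg, function(th)
    sum(pair_loglik_diffusive(pd$t1, pd$t2, th, 1, 1, env)), numeric(1))
  expect_lt(abs(thg[which.max(lls)] - (-1.5)), 0.51)
})
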