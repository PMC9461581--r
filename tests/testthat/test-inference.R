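# Bayesian machinery: posterior, MAP determinism, relative error, marginal
# likelihoods, Bayes factors, confusion bookkeeping.

test_that("log posterior applies the prior box and sums pair likelihoods", {
  env <- ref_env()
  prior <- prior_box()
  d <- simulate_dataset(two_agent("none", -1),
                        sim_settings(dt = 0.01, t_max = 120, n_trials = 20,
                                     seed = 61))
  p <- departure_pairs(d)
  expect_identical(log_posterior(p, list(theta = -6, B = 1), "none", prior, env),
                   -Inf)
  expect_identical(log_posterior(p, list(theta = -1, B = 5), "none", prior, env),
                   -Inf)
  # single observation equals that pair's log likelihood plus the prior const
  one <- p[1, ]
  lp <- log_posterior(one, list(theta = -1, B = 1), "none", prior, env)
  ll <- pair_loglik_none(one$t1, one$t2, -1, 1, env)
  expect_equal(lp, ll + socforage:::log_prior_const("none", prior))
  # generating parameters beat a distant point on simulated data
  d2 <- simulate_dataset(two_agent("none", -1),
                         sim_settings(dt = 0.01, t_max = 120, n_trials = 150,
                                      seed = 62))
  p2 <- departure_pairs(d2)
  expect_gt(log_posterior(p2, list(theta = -1, B = 1), "none", prior, env),
            log_posterior(p2, list(theta = -4, B = 3), "none", prior, env))
  expect_error(log_posterior(p2[0, ], list(theta = -1, B = 1), "none", prior,
                             env), "empty")
})

test_that("MAP estimation is deterministic and stays inside the prior", {
  env <- ref_env()
  prior <- prior_box()
  d <- simulate_dataset(two_agent("none", -1.2, B = 1.5),
                        sim_settings(dt = 0.01, t_max = 120, n_trials = 120,
                                     seed = 63))
  p <- departure_pairs(d)
  f1 <- map_estimate(p, "none", prior, env)
  f2 <- map_estimate(p, "none", prior, env)
  expect_identical(f1$estimate, f2$estimate)
  expect_gte(f1$estimate[["theta"]], prior$theta[1])
  expect_lte(f1$estimate[["theta"]], prior$theta[2])
  expect_gte(f1$estimate[["B"]], prior$B[1])
  # and it lands in the right region
  expect_lt(abs(f1$estimate[["theta"]] - (-1.2)), 1)
  expect_lt(abs(f1$estimate[["B"]] - 1.5), 1.2)
})

test_that("relative error matches the printed arithmetic", {
  truth <- c(theta = -1, kappa = 2, B = 1)
  expect_equal(relative_error(truth, truth, "diffusive"), 0)
  est <- c(theta = -2, kappa = 2, B = 1)
  expect_equal(relative_error(est, truth, "diffusive"), 1 / 3)
  # two-term analogue for the uncoupled class
  expect_equal(relative_error(c(theta = -1, B = 1.5), c(theta = -1, B = 1),
                              "none"), 0.25)
  # invariant to joint rescaling
  expect_equal(relative_error(2 * est, 2 * truth, "diffusive"),
               relative_error(est, truth, "diffusive"))
  expect_error(relative_error(est, c(theta = -1, kappa = 0, B = 1),
                              "diffusive"), "non-zero")
})

test_that("marginal likelihood is stabilised Monte Carlo over the prior", {
  env <- ref_env()
  prior <- prior_box()
  d <- simulate_dataset(two_agent("none", -1),
                        sim_settings(dt = 0.01, t_max = 120, n_trials = 30,
                                     seed = 64))
  p <- departure_pairs(d)
  # single prior sample reduces to that sample's log likelihood
  m1 <- log_marginal_likelihood(p, "none", prior, env, n_prior_samples = 1,
                                seed = 7)
  draw <- socforage:::with_preserved_rng(7, {
    list(theta = runif(1, prior$theta[1], prior$theta[2]),
         B = runif(1, prior$B[1], prior$B[2]))
  })
  expect_equal(as.numeric(m1),
               sum(pair_loglik_none(p$t1, p$t2, draw$theta, draw$B, env,
                                    control = likelihood_control(sim_tol = 0.01))))
  # estimates stabilise as the number of prior draws grows
  m_small <- vapply(1:4, function(s)
    as.numeric(log_marginal_likelihood(p, "none", prior, env, 8, seed = s)),
    numeric(1))
  m_big <- vapply(1:4, function(s)
    as.numeric(log_marginal_likelihood(p, "none", prior, env, 64, seed = s)),
    numeric(1))
  expect_lt(sd(m_big), sd(m_small) + 1e-9)
  # R's global RNG state is untouched
  set.seed(1); before <- runif(1)
  set.seed(1)
  invisible(log_marginal_likelihood(p, "none", prior, env, 4, seed = 3))
  expect_identical(runif(1), before)
})

test_that("Bayes factors are antisymmetric and identify strong signal", {
  env <- ref_env()
  prior <- prior_box()
  d <- simulate_dataset(two_agent("none", -1),
                        sim_settings(dt = 0.01, t_max = 120, n_trials = 50,
                                     seed = 65))
  p <- departure_pairs(d)
  expect_identical(log_bayes_factor(p, "none", "none", prior, env,
                                    n_prior_samples = 6, seed = 2), 0)
  b12 <- log_bayes_factor(p, "none", "pulsatile", prior, env,
                          n_prior_samples = 10, seed = 2)
  b21 <- log_bayes_factor(p, "pulsatile", "none", prior, env,
                          n_prior_samples = 10, seed = 2)
  expect_equal(b12, -b21)
  # pulsatile data with a strong pulse is evidence against no coupling
  dp <- simulate_dataset(two_agent("pulsatile", -1.5, kappa = 3),
                         sim_settings(dt = 0.01, t_max = 120, n_trials = 50,
                                      seed = 66))
  pp <- departure_pairs(dp)
  expect_gt(log_bayes_factor(pp, "pulsatile", "none", prior, env,
                             n_prior_samples = 10, seed = 2), 0)
})

test_that("confusion bookkeeping yields normalised rows", {
  cm <- confusion_experiment(n_param_samples = 1, n_pairs = 15, seed = 99,
                             n_prior_samples = 4)
  expect_equal(dim(cm$counts), c(3, 3))
  expect_true(all(rowSums(cm$counts) == 1))
  expect_true(all(cm$fractions %in% c(0, 1)))
  expect_equal(rowSums(cm$fractions), c(none = 1, diffusive = 1,
                                        pulsatile = 1))
})
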