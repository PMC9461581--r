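# Bayesian inference on ordered departure-time pairs: uniform-box priors,
# MAP estimation by coarse grid + local refinement, relative-error scoring,
# Monte Carlo marginal likelihoods, Bayes factors and the model-class
# confusion experiment.

#' Uniform prior box over model parameters
#'
#' Independent uniform priors on the threshold, coupling strength and
#' diffusion scale. Defaults are the ranges used throughout the
#' identifiability experiments: `theta` in `[-5, -0.1]`, `kappa` in
#' `[0.1, 6]`, `B` in `[0.1, 4]`.
#'
#' @param theta,kappa,B Length-2 ranges (theta entirely negative).
#' @export
prior_box <- function(theta = c(-5, -0.1), kappa = c(0.1, 6),
                      B = c(0.1, 4)) {
  theta <- sort(theta); kappa <- sort(kappa); B <- sort(B)
  stopifnot(theta[2] < 0, kappa[1] >= 0, B[1] > 0,
            diff(theta) > 0, diff(kappa) > 0, diff(B) > 0)
  structure(list(theta = theta, kappa = kappa, B = B), class = "prior_box")
}

model_class_params <- function(model_class) {
  if (model_class == "none") c("theta", "B") else c("theta", "kappa", "B")
}

in_prior <- function(params, model_class, prior) {
  for (p in model_class_params(model_class)) {
    r <- prior[[p]]
    if (params[[p]] < r[1] || params[[p]] > r[2]) return(FALSE)
  }
  TRUE
}

log_prior_const <- function(model_class, prior) {
  -sum(vapply(model_class_params(model_class),
              function(p) log(diff(prior[[p]])), numeric(1)))
}

with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

as_pairs <- function(dataset) {
  if (!is.null(dataset$t1)) dataset else departure_pairs(dataset)
}

#' Log posterior of model parameters given departure-time pairs
#'
#' Sum of per-pair log likelihoods (the observation pairs are independent
#' bouts) plus the log prior, which is constant inside the prior box and
#' `-Inf` outside; the marginal over the data is dropped.
#'
#' @param dataset A `departure_dataset` or pairs data frame (`t1`, `t2`,
#'   optionally `simultaneous`).
#' @param params Named list/vector with `theta`, `B` and (for coupled
#'   classes) `kappa`.
#' @param model_class `"none"`, `"diffusive"` or `"pulsatile"`.
#' @param prior A [prior_box()].
#' @param env A [patch_env()] (patch parameters are treated as known).
#' @param control A [likelihood_control()].
#' @export
log_posterior <- function(dataset, params, model_class, prior, env,
                          control = likelihood_control()) {
  pairs <- as_pairs(dataset)
  if (nrow(pairs) == 0) stop("log_posterior: empty dataset")
  params <- as.list(params)
  if (!in_prior(params, model_class, prior)) return(-Inf)
  sum(loglik_pairs(pairs, params, model_class, env, control)) +
    log_prior_const(model_class, prior)
}

#' MAP search specification
#'
#' Coarse grid resolutions per parameter plus local refinement: each pass
#' re-grids a shrinking box around the incumbent with `n_refine` points per
#' dimension.
#' @param n_theta,n_kappa,n_B Coarse grid sizes.
#' @param n_refine Points per dimension in each refinement pass.
#' @param refine_passes Number of refinement passes.
#' @export
map_search_spec <- function(n_theta = 5, n_kappa = 4, n_B = 4,
                            n_refine = 3, refine_passes = 2) {
  structure(list(n_theta = n_theta, n_kappa = n_kappa, n_B = n_B,
                 n_refine = n_refine, refine_passes = refine_passes),
            class = "map_search_spec")
}

#' Maximum a posteriori parameter estimate
#'
#' Grid search inside the prior box (coarse lattice, then local
#' refinement passes that halve the spacing around the incumbent), using
#' the class's likelihood backend. Deterministic given the dataset, the
#' search spec and the likelihood seed.
#'
#' @inheritParams log_posterior
#' @param search A [map_search_spec()].
#' @return An object of class `map_fit`: named `estimate`, `log_posterior`
#'   at the mode, the evaluation `trace`, and the model class.
#' @export
map_estimate <- function(dataset, model_class, prior, env,
                         control = likelihood_control(),
                         search = map_search_spec()) {
  pairs <- as_pairs(dataset)
  if (nrow(pairs) == 0) stop("map_estimate: empty dataset")
  pnames <- model_class_params(model_class)
  grids <- list(
    theta = seq(prior$theta[1], prior$theta[2], length.out = search$n_theta),
    kappa = seq(prior$kappa[1], prior$kappa[2], length.out = search$n_kappa),
    B = seq(prior$B[1], prior$B[2], length.out = search$n_B))
  lp_const <- log_prior_const(model_class, prior)
  eval_point <- function(pt) {
    sum(loglik_pairs(pairs, pt, model_class, env, control)) + lp_const
  }
  run_grid <- function(gr) {
    pts <- expand.grid(gr[pnames], KEEP.OUT.ATTRS = FALSE)
    ll <- apply(pts, 1, function(row) eval_point(as.list(row)))
    cbind(pts, logpost = ll)
  }
  trace <- run_grid(grids)
  best <- trace[which.max(trace$logpost), ]
  spacing <- vapply(pnames, function(p) {
    g <- grids[[p]]
    if (length(g) > 1) g[2] - g[1] else diff(prior[[p]])
  }, numeric(1))
  for (pass in seq_len(search$refine_passes)) {
    spacing <- spacing / 2
    gr <- lapply(pnames, function(p) {
      ctr <- best[[p]]
      g <- seq(ctr - spacing[[p]], ctr + spacing[[p]],
               length.out = search$n_refine)
      pmin(pmax(g, prior[[p]][1]), prior[[p]][2])
    })
    names(gr) <- pnames
    tr <- run_grid(gr)
    trace <- rbind(trace, tr)
    cand <- tr[which.max(tr$logpost), ]
    if (cand$logpost > best$logpost) best <- cand
  }
  if (!is.finite(best$logpost))
    stop("map_estimate: posterior is degenerate (all evaluations non-finite)")
  est <- vapply(pnames, function(p) best[[p]], numeric(1))
  structure(list(estimate = est, log_posterior = best$logpost,
                 model_class = model_class, trace = trace),
            class = "map_fit")
}

#' @export
print.map_fit <- function(x, ...) {
  cat(sprintf("<map_fit> class = %s, log posterior = %.3f\n",
              x$model_class, x$log_posterior))
  print(signif(x$estimate, 4))
  invisible(x)
}

#' Mean absolute relative error of a parameter estimate
#'
#' \eqn{\frac{1}{3}\left(\frac{|\hat\theta - \theta|}{|\theta|} +
#' \frac{|\hat B - B|}{B} + \frac{|\hat\kappa - \kappa|}{\kappa}\right)}
#' for coupled classes; the two-term analogue (theta, B) for the
#' no-coupling class.
#'
#' @param estimate,truth Named vectors/lists with the class's parameters.
#' @param model_class `"none"`, `"diffusive"` or `"pulsatile"`.
#' @export
relative_error <- function(estimate, truth, model_class) {
  estimate <- as.list(estimate)
  truth <- as.list(truth)
  pnames <- model_class_params(model_class)
  tv <- vapply(pnames, function(p) as.numeric(truth[[p]]), numeric(1))
  if (any(tv == 0)) stop("relative_error: truth components must be non-zero")
  ev <- vapply(pnames, function(p) as.numeric(estimate[[p]]), numeric(1))
  mean(abs(ev - tv) / abs(tv))
}

#' Monte Carlo log marginal likelihood of a model class
#'
#' Simple Monte Carlo over the uniform prior: draws `n_prior_samples`
#' parameter sets, evaluates the dataset log likelihood at each, and
#' returns the log of their average (log-sum-exp stabilised). The
#' attribute `mc_se` carries the linear-scale relative standard error.
#'
#' @inheritParams log_posterior
#' @param n_prior_samples Number of prior draws (>= 1).
#' @param seed Seed for the prior draws (R's RNG state is restored).
#' @export
log_marginal_likelihood <- function(dataset, model_class, prior, env,
                                    n_prior_samples = 24, seed = 1,
                                    control = likelihood_control()) {
  pairs <- as_pairs(dataset)
  if (nrow(pairs) == 0) stop("log_marginal_likelihood: empty dataset")
  pnames <- model_class_params(model_class)
  draws <- with_preserved_rng(seed, {
    lapply(seq_len(n_prior_samples), function(i) {
      pt <- lapply(pnames, function(p) runif(1, prior[[p]][1], prior[[p]][2]))
      names(pt) <- pnames
      pt
    })
  })
  ll <- vapply(draws, function(pt)
    sum(loglik_pairs(pairs, pt, model_class, env, control)), numeric(1))
  if (all(!is.finite(ll)))
    stop("log_marginal_likelihood: all prior samples have -Inf likelihood")
  m <- max(ll)
  w <- exp(ll - m)
  est <- m + log(mean(w))
  se <- if (n_prior_samples > 1) sd(w) / (sqrt(n_prior_samples) * mean(w)) else NA_real_
  structure(est, mc_se = se)
}

#' Log Bayes factor between two model classes
#'
#' Difference of Monte Carlo log marginal likelihoods with equal prior
#' model probabilities; positive values favour `class_1`. The prior draws
#' for a class depend only on the class (not its position), so the Bayes
#' factor is antisymmetric and comparing a class against itself gives
#' exactly zero.
#'
#' @inheritParams log_marginal_likelihood
#' @param class_1,class_2 Model classes.
#' @export
log_bayes_factor <- function(dataset, class_1, class_2, prior, env,
                             n_prior_samples = 24, seed = 1,
                             control = likelihood_control()) {
  classes <- c("none", "diffusive", "pulsatile")
  s1 <- derive_seed(seed, match(class_1, classes))
  s2 <- derive_seed(seed, match(class_2, classes))
  m1 <- log_marginal_likelihood(dataset, class_1, prior, env,
                                n_prior_samples, s1, control)
  m2 <- log_marginal_likelihood(dataset, class_2, prior, env,
                                n_prior_samples, s2, control)
  as.numeric(m1) - as.numeric(m2)
}

#' Model-identifiability confusion experiment
#'
#' For each true model class: draw parameters from the prior, simulate a
#' dataset of `n_pairs` departure-time pairs, and classify it as the class
#' with the largest Monte Carlo log marginal likelihood (ties resolve in
#' the fixed order none < diffusive < pulsatile). Returns counts and
#' row-normalised fractions.
#'
#' @param n_param_samples Prior draws per true class (>= 1).
#' @param n_pairs Pairs per simulated dataset.
#' @param prior A [prior_box()].
#' @param env A [patch_env()].
#' @param seed Root seed (dataset seeds and prior-draw seeds derive from
#'   it).
#' @param n_prior_samples Prior draws per marginal-likelihood estimate.
#' @param gen_settings Generator settings template (dt, t_max).
#' @param control A [likelihood_control()].
#' @return An object of class `confusion_matrix` with `counts`,
#'   `fractions` (rows sum to 1) and the per-cell dataset seeds.
#' @export
confusion_experiment <- function(n_param_samples, n_pairs,
                                 prior = prior_box(),
                                 env = patch_env(2, 5, 1, 5), seed = 1,
                                 n_prior_samples = 24,
                                 gen_settings = sim_settings(dt = 0.01,
                                                             t_max = 400),
                                 control = likelihood_control()) {
  stopifnot(n_param_samples >= 1)
  classes <- c("none", "diffusive", "pulsatile")
  counts <- matrix(0L, 3, 3, dimnames = list(true = classes,
                                             predicted = classes))
  seeds <- matrix(NA_real_, n_param_samples, 3,
                  dimnames = list(NULL, classes))
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    pnames <- model_class_params(cls)
    for (k in seq_len(n_param_samples)) {
      dseed <- derive_seed(seed, ci * 10000 + k)
      seeds[k, ci] <- dseed
      pt <- with_preserved_rng(dseed, {
        out <- lapply(pnames, function(p) runif(1, prior[[p]][1], prior[[p]][2]))
        names(out) <- pnames
        out
      })
      model <- group_model(
        mode = cls, env,
        theta = rep(pt$theta, 2),
        kappa = if (cls == "none") 0 else pt$kappa,
        noise_scale = pt$B)
      ds <- simulate_dataset(model, sim_settings(dt = gen_settings$dt,
                                                 t_max = gen_settings$t_max,
                                                 n_trials = n_pairs,
                                                 seed = dseed))
      pairs <- departure_pairs(ds)
      lml <- vapply(seq_along(classes), function(mj)
        as.numeric(log_marginal_likelihood(pairs, classes[mj], prior, env,
                                           n_prior_samples,
                                           derive_seed(dseed, mj), control)),
        numeric(1))
      pred <- which.max(lml) # ties: fixed order none < diffusive < pulsatile
      counts[ci, pred] <- counts[ci, pred] + 1L
    }
  }
  fractions <- counts / rowSums(counts)
  structure(list(counts = counts, fractions = fractions, seeds = seeds,
                 n_pairs = n_pairs, n_param_samples = n_param_samples),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d parameter draws per class, n = %d pairs each\n",
              x$n_param_samples, x$n_pairs))
  print(round(x$fractions, 3))
  invisible(x)
}
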