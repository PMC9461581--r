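# Reward accounting and strategy evaluation: total food consumed up to the
# group departure, reward rate, limit-case comparisons, symmetric
# (theta, kappa) sweeps and asymmetric partner optimisation. All sweeps use
# grid search with common random numbers across cells so that arg-max
# comparisons are not dominated by Monte Carlo noise.

#' Total food consumed by the group in one bout
#'
#' Implements the telescoping closed form
#' \deqn{r_N(T) = \rho\tau\left[(1 - e^{-N T_1/\tau}) +
#'   e^{-N T_1/\tau}(1 - e^{-(N-1)(T_2-T_1)/\tau}) + \cdots\right],}
#' the integral of the group consumption rate
#' \eqn{\mathcal{N}(t)\,\rho e^{-\Lambda(t)}} up to the last decision.
#' Never exceeds the total patch content \eqn{\rho\tau}.
#'
#' @param record A [departure_record()] or a sorted numeric vector of
#'   decision times.
#' @param env A [patch_env()].
#' @param n Group size (taken from the record if omitted).
#' @return Energy consumed by the whole group up to `T_N`.
#' @examples
#' env <- patch_env(2, 5, 1)
#' total_food_consumed(c(3, 4), env)        # two foragers
#' env$rho * env$tau                        # the whole patch
#' @export
total_food_consumed <- function(record, env, n = NULL) {
  ts <- if (inherits(record, "departure_record")) record$ordered_times else record
  if (is.unsorted(ts)) stop("total_food_consumed: decision times must be sorted")
  if (is.null(n)) n <- length(ts)
  prev <- 0
  acc <- 0
  carry <- 1
  for (j in seq_along(ts)) {
    nj <- n - j + 1
    e <- exp(-nj * (ts[j] - prev) / env$tau)
    acc <- acc + carry * (1 - e)
    carry <- carry * e
    prev <- ts[j]
  }
  env$rho * env$tau * acc
}

#' Reward rate of a foraging strategy
#'
#' \deqn{RR = \frac{\langle r_N \rangle - \alpha (T_I + \langle T \rangle)}
#'                 {T_I + \langle T \rangle},}
#' the mean net energy per unit time over a patch visit plus the travel to
#' the next patch. Means are taken separately over realisations
#' (ratio of means, as the strategy-efficiency criterion is defined).
#'
#' @param mean_reward Mean total food consumed per bout.
#' @param mean_group_time Mean group departure time.
#' @param env A [patch_env()] (supplies `alpha` and `travel_time`).
#' @export
reward_rate <- function(mean_reward, mean_group_time, env) {
  if (mean_group_time < 0) stop("reward_rate: mean_group_time must be >= 0")
  denom <- env$travel_time + mean_group_time
  if (denom <= 0) stop("reward_rate: travel_time + mean time must be positive")
  (mean_reward - env$alpha * denom) / denom
}

#' Monte Carlo reward-rate estimate for a group strategy
#'
#' Simulates `settings$n_trials` bouts, accumulates per-bout reward and
#' group time, and returns the reward rate with a delta-method standard
#' error for the ratio of means.
#'
#' @param model A [group_model()].
#' @param settings A [sim_settings()].
#' @return List of class `strategy_eval`: `rr`, `se`, `mean_reward`,
#'   `mean_time`, `n_trials`.
#' @export
evaluate_strategy <- function(model, settings = sim_settings()) {
  ds <- simulate_dataset(model, settings)
  pairs_by_trial <- split(ds$decision_time, ds$trial)
  Tn <- vapply(pairs_by_trial, max, numeric(1))
  r <- vapply(pairs_by_trial, function(tt)
    total_food_consumed(sort(tt), model$env), numeric(1))
  rr_from_sums(r, Tn, model$env, settings$n_trials)
}

rr_from_sums <- function(r, Tn, env, n) {
  rbar <- mean(r)
  tbar <- mean(Tn)
  denom <- env$travel_time + tbar
  rr <- rbar / denom - env$alpha
  g <- c(1 / denom, -rbar / denom^2)       # gradient wrt (rbar, tbar)
  V <- stats::cov(cbind(r, Tn)) / n
  se <- sqrt(drop(t(g) %*% V %*% g))
  structure(list(rr = rr, se = se, mean_reward = rbar, mean_time = tbar,
                 n_trials = n),
            class = "strategy_eval")
}

#' @export
print.strategy_eval <- function(x, ...) {
  cat(sprintf("<strategy_eval> RR = %.4f (se %.4f), mean reward %.3f, mean group time %.3f (n = %d)\n",
              x$rr, x$se, x$mean_reward, x$mean_time, x$n_trials))
  invisible(x)
}

#' Reward rate of a limiting two-coupling case
#'
#' Evaluates the no-coupling (`"NC"`), perfect-diffusive (`"D_inf"`) or
#' perfect-pulsatile (`"P_inf"`) limit by simulation. `D_inf` uses the
#' exact one-dimensional reduction (shared belief, `n`-forager depletion
#' drift, half the diffusion); `P_inf` is realised by pulses spanning the
#' whole belief range (`kappa = |theta| + 1`), so every bout departs at the
#' minimum first passage time; `NC` runs the full uncoupled group. The
#' group reward uses the exact depletion accounting in every case.
#'
#' @param case `"NC"`, `"D_inf"` or `"P_inf"`.
#' @param env A [patch_env()].
#' @param theta Common departure threshold (< 0).
#' @param B Individual belief diffusion scale.
#' @param n Group size.
#' @param settings A [sim_settings()].
#' @return A `strategy_eval`.
#' @export
evaluate_limit_case <- function(case = c("NC", "D_inf", "P_inf"), env, theta,
                                B, n = 2, settings = sim_settings()) {
  case <- match.arg(case)
  if (case == "D_inf") {
    # shared belief: depletion exponent n*t/tau via tau/n, diffusion B/2
    env1 <- patch_env(env$rho, env$tau / n, env$alpha, env$travel_time)
    m <- group_model("none", env1, theta = theta, noise_scale = B / 2)
    ds <- simulate_dataset(m, settings)
    Tn <- ds$decision_time
    r <- env$rho * env$tau * (1 - exp(-n * Tn / env$tau)) # all n forage to Tn
    return(rr_from_sums(r, Tn, env, settings$n_trials))
  }
  model <- switch(case,
    NC = group_model("none", env, theta = rep(theta, n), noise_scale = B),
    # a pulse spanning the whole attainable belief range: the first decider
    # always triggers everyone (a pulse of just |theta| would miss beliefs
    # that have risen above the starting point)
    P_inf = group_model("pulsatile", env, theta = rep(theta, n),
                        kappa = 1e6, noise_scale = B))
  evaluate_strategy(model, settings)
}

#' Compare limiting coupling cases at their best thresholds
#'
#' For each limiting case, evaluates the reward rate over a grid of
#' departure thresholds with common random numbers and reports the best.
#'
#' @inheritParams evaluate_limit_case
#' @param theta_grid Thresholds to scan (all < 0).
#' @param cases Which limits to evaluate.
#' @return Data frame with one row per case: best `theta`, `rr`, `se`.
#' @export
compare_limit_cases <- function(env, theta_grid, B, n = 2,
                                settings = sim_settings(),
                                cases = c("NC", "D_inf", "P_inf")) {
  stopifnot(all(theta_grid < 0))
  rows <- lapply(cases, function(cs) {
    evs <- lapply(theta_grid, function(th)
      evaluate_limit_case(cs, env, th, B, n, settings))
    rr <- vapply(evs, `[[`, numeric(1), "rr")
    best <- which.max(rr)
    data.frame(case = cs, theta = theta_grid[best], rr = rr[best],
               se = evs[[best]]$se)
  })
  do.call(rbind, rows)
}

# centred moving average, window 3, partial windows at the edges
smooth_window3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out[1] <- mean(x[1:2])
  out[n] <- mean(x[(n - 1):n])
  out
}

#' Symmetric strategy sweep over threshold and coupling strength
#'
#' Evaluates the reward rate of a homogeneous group on a
#' `theta_grid x kappa_grid` lattice (common random numbers across cells)
#' and extracts the optimal-threshold curve per coupling strength, smoothed
#' by a sliding window of length 3. Optionally appends the infinite-
#' coupling column computed from the corresponding limiting model.
#'
#' @param mode `"diffusive"` or `"pulsatile"`.
#' @param env A [patch_env()].
#' @param theta_grid,kappa_grid Non-empty grids.
#' @param B Belief diffusion scale.
#' @param n Group size.
#' @param settings A [sim_settings()].
#' @param include_infinite Append a `kappa = Inf` column from the
#'   corresponding limit (`D_inf` or `P_inf`).
#' @return An object of class `strategy_sweep`: long-format `surface`
#'   (`theta`, `kappa`, `rr`, `se`) and `optimal_theta` per `kappa`
#'   (raw and smoothed).
#' @export
sweep_symmetric <- function(mode = c("diffusive", "pulsatile"), env,
                            theta_grid, kappa_grid, B, n = 2,
                            settings = sim_settings(),
                            include_infinite = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(theta_grid) >= 1, length(kappa_grid) >= 1)
  rows <- list()
  for (ka in kappa_grid) {
    for (th in theta_grid) {
      m <- group_model(mode, env, theta = rep(th, n), kappa = ka,
                       noise_scale = B)
      ev <- evaluate_strategy(m, settings)
      rows[[length(rows) + 1L]] <-
        data.frame(theta = th, kappa = ka, rr = ev$rr, se = ev$se)
    }
  }
  if (include_infinite) {
    lim <- if (mode == "diffusive") "D_inf" else "P_inf"
    for (th in theta_grid) {
      ev <- evaluate_limit_case(lim, env, th, B, n, settings)
      rows[[length(rows) + 1L]] <-
        data.frame(theta = th, kappa = Inf, rr = ev$rr, se = ev$se)
    }
  }
  surface <- do.call(rbind, rows)
  kv <- unique(surface$kappa)
  opt <- vapply(kv, function(ka) {
    s <- surface[surface$kappa == ka, ]
    s$theta[which.max(s$rr)]
  }, numeric(1))
  structure(list(surface = surface,
                 optimal_theta = data.frame(kappa = kv, theta_opt = opt,
                                            theta_opt_smooth = smooth_window3(opt)),
                 mode = mode, n_trials = settings$n_trials,
                 seed = settings$seed),
            class = "strategy_sweep")
}

#' @export
print.strategy_sweep <- function(x, ...) {
  cat(sprintf("<strategy_sweep> mode = %s, %d cells, n_trials/cell = %d\n",
              x$mode, nrow(x$surface), x$n_trials))
  best <- x$surface[which.max(x$surface$rr), ]
  cat(sprintf("  best RR = %.4f at theta = %g, kappa = %g\n",
              best$rr, best$theta, best$kappa))
  invisible(x)
}

#' Optimise a partner's strategy against a fixed agent
#'
#' Grid search over the free agent's `(theta2, kappa2)` with common random
#' numbers; ties resolve to the smallest `|theta2|`, then the smallest
#' `kappa2` (the grid is scanned in that order and only strict
#' improvements move the arg-max).
#'
#' @param fixed_agent An [agent_strategy()] for agent 1.
#' @param theta_grid,kappa_grid Grids for the free agent.
#' @param mode `"diffusive"` or `"pulsatile"`.
#' @param env A [patch_env()].
#' @param B Belief diffusion scale.
#' @param settings A [sim_settings()].
#' @return List with `theta2`, `kappa2`, `rr`, `se` and the full `surface`.
#' @export
optimize_partner <- function(fixed_agent, theta_grid, kappa_grid,
                             mode = c("diffusive", "pulsatile"), env, B,
                             settings = sim_settings()) {
  mode <- match.arg(mode)
  stopifnot(length(theta_grid) >= 1, length(kappa_grid) >= 1)
  ord_theta <- theta_grid[order(abs(theta_grid))]
  ord_kappa <- sort(kappa_grid)
  best <- NULL
  rows <- list()
  for (th in ord_theta) {
    for (ka in ord_kappa) {
      m <- group_model(mode, env,
                       agents = list(fixed_agent, agent_strategy(th, ka)),
                       noise_scale = B)
      ev <- evaluate_strategy(m, settings)
      rows[[length(rows) + 1L]] <-
        data.frame(theta2 = th, kappa2 = ka, rr = ev$rr, se = ev$se)
      if (is.null(best) || ev$rr > best$rr)
        best <- list(theta2 = th, kappa2 = ka, rr = ev$rr, se = ev$se)
    }
  }
  c(best, list(surface = do.call(rbind, rows)))
}
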