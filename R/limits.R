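# Limiting models for a homogeneous group: no coupling (NC), perfect
# diffusive coupling (D_inf, shared belief with half the diffusion), and
# perfect pulsatile coupling (P_inf, group departs at the minimum of N
# i.i.d. first passage times), plus the Ornstein-Uhlenbeck analysis of the
# half-difference of two diffusively coupled beliefs.

#' Variance of the belief half-difference under diffusive coupling
#'
#' For two diffusively coupled agents with equal thresholds and no
#' resource drift, the half-difference \eqn{x_- = (x_1 - x_2)/2} is an
#' Ornstein-Uhlenbeck process relaxing at rate \eqn{2\kappa} with
#' \eqn{\mathrm{Var}(x_-)(t) = \frac{B}{4\kappa}(1 - e^{-4\kappa t})}.
#' Diffusive coupling therefore cancels the belief disagreement entirely
#' in the strong-coupling limit.
#'
#' @param kappa Coupling strength (> 0).
#' @param B Diffusion scale of each belief.
#' @param t Time(s), non-negative.
#' @export
ou_half_difference_variance <- function(kappa, B, t) {
  if (!(kappa > 0)) stop("ou_half_difference_variance: kappa must be positive")
  if (any(t < 0)) stop("ou_half_difference_variance: t must be non-negative")
  B / (4 * kappa) * (1 - exp(-4 * kappa * t))
}

#' Monte Carlo samples of the belief half-difference
#'
#' Simulates two diffusively coupled agents with `rho = alpha = 0` and no
#' absorbing boundary, returning samples of \eqn{(x_1 - x_2)/2} at the
#' requested times. Used to verify the [ou_half_difference_variance()]
#' analytics against the full Euler-Maruyama engine.
#'
#' @inheritParams ou_half_difference_variance
#' @param times Increasing record times.
#' @param n_trials Number of independent pairs.
#' @param dt Euler step.
#' @param seed Root seed.
#' @return Matrix `n_trials x length(times)` of half-difference samples.
#' @export
simulate_half_difference <- function(kappa, B, times, n_trials = 1000,
                                     dt = 0.005, seed = 1) {
  stopifnot(kappa >= 0, B > 0, !is.unsorted(times), n_trials >= 1)
  cpp_simulate_half_difference(kappa, B, dt, as.numeric(times),
                               as.integer(n_trials), as.numeric(seed))
}

# shared backend: single-process FPT density under the m-forager depletion
# drift with diffusion coefficient D
limit_single_fpt <- function(env, theta, D, m, t_max, grid, mass_tol = 1e-3) {
  grid <- auto_grid(env, theta, D, grid)
  if (is.null(t_max)) {
    xfree <- function(t) env$rho * env$tau / m * (1 - exp(-m * t / env$tau)) -
      env$alpha * t
    t_peak <- env$tau / m * log(env$rho / env$alpha)
    t_hi <- t_peak + (xfree(t_peak) - theta) / env$alpha + 2 * env$tau
    t_char <- tryCatch(uniroot(function(t) xfree(t) - theta,
                               c(t_peak, t_hi))$root,
                       error = function(e) t_hi)
    t_max <- 1.6 * t_char + 14 * sqrt(max(D, 0.05)) + 6 * env$tau / m
  }
  res <- cpp_fpt_exp_drift(env$rho, env$tau, env$alpha, m, 0, D, theta,
                           grid$x_max, grid$nx, grid$dt_pde, t_max, 0)
  list(t = res$t, f = res$f, S = res$S, grid = grid, t_max = t_max)
}

#' First-passage density of the perfectly diffusively coupled group
#'
#' In the strong-coupling limit all beliefs collapse onto their average,
#' which obeys a single drift-diffusion equation with the `n`-forager
#' depletion drift and *half* the diffusion of an individual belief
#' (`sqrt(B) dW` instead of `sqrt(2B) dW`): diffusive coupling averages out
#' half the noise. The group departure time is this single first passage
#' time.
#'
#' @param env A [patch_env()].
#' @param theta Common departure threshold (< 0).
#' @param B Diffusion scale of an individual belief.
#' @param n Group size.
#' @param t_max Horizon (auto if `NULL`); a truncation warning reports the
#'   captured mass if the horizon is too short.
#' @param grid A [grid_spec()].
#' @return An [fpt_density()] of the group departure time.
#' @export
d_infinity_fpt <- function(env, theta, B, n = 2, t_max = NULL,
                           grid = grid_spec()) {
  stopifnot(theta < 0, B > 0)
  out <- limit_single_fpt(env, theta, D = B / 2, m = n, t_max, grid)
  fd <- fpt_density(out$t, out$f, out$S)
  if (attr(fd, "captured") < 0.999)
    warning(sprintf("d_infinity_fpt: captured mass %.4f; increase t_max",
                    attr(fd, "captured")))
  fd
}

#' Group first-passage density under perfect pulsatile coupling
#'
#' The first decider instantly triggers everyone else, so the group time is
#' the minimum of `n` i.i.d. first passage times of the full-noise process
#' (`sqrt(2B) dW`) with the `n`-forager depletion drift:
#' \eqn{f_{\min}(t) = n f(t) S(t)^{n-1}}.
#'
#' @inheritParams d_infinity_fpt
#' @return An [fpt_density()] of the group (minimum) departure time.
#' @export
p_infinity_group_fpt <- function(env, theta, B, n = 2, t_max = NULL,
                                 grid = grid_spec()) {
  stopifnot(theta < 0, B > 0)
  out <- limit_single_fpt(env, theta, D = B, m = n, t_max, grid)
  fmin <- n * out$f * out$S^(n - 1)
  Smin <- out$S^n
  fd <- fpt_density(out$t, fmin, Smin)
  if (attr(fd, "captured") < 0.995)
    warning(sprintf("p_infinity_group_fpt: captured mass %.4f; increase t_max",
                    attr(fd, "captured")))
  fd
}

#' Group first-passage density with no coupling
#'
#' With independent deciders the group departs at the *maximum* decision
#' time, and the depletion drift switches when the first forager stops.
#' For `n = 2` the density is computed by exact propagation: first-decider
#' flux under the two-forager drift, then conditional propagation of the
#' survivor's interior density under the one-forager drift. For `n > 2`
#' a Monte Carlo histogram is returned.
#'
#' @inheritParams d_infinity_fpt
#' @param stride Snapshot stride (in PDE steps) for the first-decision
#'   integral (`n = 2` only).
#' @param n_trials Monte Carlo size for `n > 2`.
#' @param seed Seed for the Monte Carlo branch.
#' @return An [fpt_density()] of the group (maximum) departure time.
#' @export
nc_group_fpt <- function(env, theta, B, n = 2, t_max = NULL,
                         grid = grid_spec(), stride = 3,
                         n_trials = 20000, seed = 1) {
  stopifnot(theta < 0, B > 0)
  if (n == 2) {
    D <- B
    grid <- auto_grid(env, theta, D, grid)
    if (is.null(t_max)) {
      base <- limit_single_fpt(env, theta, D, m = 1, t_max = NULL, grid)
      t_max <- 1.4 * base$t_max # the max of two times has a longer tail
    }
    res <- cpp_nc_group_fpt(env$rho, env$tau, env$alpha, theta, B,
                            grid$dt_pde, grid$nx, grid$x_max, t_max,
                            as.integer(stride))
    dtp <- grid$dt_pde
    Sg <- pmax(1 - cumsum(res$g) * dtp, 0)
    fd <- fpt_density(res$t, res$g, Sg)
    if (attr(fd, "captured") < 0.98)
      warning(sprintf("nc_group_fpt: captured mass %.4f; increase t_max or reduce stride",
                      attr(fd, "captured")))
    return(fd)
  }
  model <- group_model("none", env, theta = rep(theta, n),
                       noise_scale = B)
  ds <- simulate_dataset(model, sim_settings(dt = 0.01,
                                             t_max = t_max %||% 400,
                                             n_trials = n_trials,
                                             seed = seed))
  hh <- empirical_departure_distribution(ds, bin_width = 0.25)
  fpt_density(hh$mids, hh$density, pmax(1 - cumsum(hh$density) * 0.25, 0))
}
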