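# Pair-likelihood backends for ordered departure-time pairs (T1 <= T2) of
# a two-forager group. The no-coupling and pulsatile classes factor across
# the first decision and are computed by exact Fokker-Planck propagation;
# the diffusive class is genuinely two-dimensional before the first
# decision and uses a seeded simulation + kernel density backend.

#' Numerical controls for the likelihood backends
#'
#' @param dt_pde Fokker-Planck time step.
#' @param nx,x_max Spatial grid (auto-chosen from the drift excursion and
#'   diffusion length when `NULL`).
#' @param sim_n Number of simulated bouts per parameter query for the
#'   diffusive backend.
#' @param sim_dt Euler step of the diffusive backend.
#' @param sim_t_max Horizon of the diffusive backend.
#' @param sim_seed Likelihood seed of the diffusive backend: the same seed
#'   is used at every parameter query within one fit, so the estimated
#'   likelihood is a deterministic function of the parameters.
#' @param sim_tol Simultaneity tolerance: observed pairs with
#'   `t2 - t1 <= sim_tol` score the pulsatile atom. Defaults to the
#'   generating Euler step when pairs come from [departure_pairs()], else
#'   to `dt_pde`.
#' @param density_floor Lower bound applied to every density factor so log
#'   likelihoods stay finite.
#' @param snap_stride Snapshot stride (in PDE steps) of the conditional
#'   propagation: pairs are grouped on snapshots taken every so-many steps
#'   at or before their first decision and propagated together, trading an
#'   O(`snap_stride * dt_pde`) drift sliver for a several-fold speed-up.
#' @export
likelihood_control <- function(dt_pde = 0.025, nx = NULL, x_max = NULL,
                               sim_n = 1000, sim_dt = 0.015, sim_t_max = 120,
                               sim_seed = 20, sim_tol = NULL,
                               density_floor = 1e-12, snap_stride = 4) {
  structure(list(dt_pde = dt_pde, nx = nx, x_max = x_max, sim_n = sim_n,
                 sim_dt = sim_dt, sim_t_max = sim_t_max, sim_seed = sim_seed,
                 sim_tol = sim_tol, density_floor = density_floor,
                 snap_stride = as.integer(snap_stride)),
            class = "likelihood_control")
}

ll_grid <- function(env, theta, B, control) {
  g <- auto_grid(env, theta, D = B,
                 grid_spec(x_max = control$x_max, nx = control$nx,
                           dt_pde = control$dt_pde))
  g
}

check_pairs <- function(t1, t2) {
  stopifnot(length(t1) == length(t2))
  if (any(t1 <= 0)) stop("pair likelihood: first decision times must be positive")
  if (any(t2 < t1)) stop("pair likelihood: need t1 <= t2 (ordered pairs)")
}

#' Log joint density of an ordered pair under no coupling
#'
#' The two beliefs evolve i.i.d. under the two-forager depletion drift
#' until the first decision; the survivor's conditional interior density is
#' then propagated under the one-forager drift. The joint density of the
#' ordered pair is `2 f(T1) g(T2 | T1)` with the survivor factor carried by
#' the unnormalised propagation.
#'
#' @param t1,t2 Ordered decision times (vectors, `0 < t1 <= t2`).
#' @param theta Common threshold (< 0).
#' @param B Belief diffusion scale.
#' @param env A [patch_env()].
#' @param control A [likelihood_control()]. Pairs with `t2 - t1` within the
#'   simultaneity tolerance score the local probability mass
#'   (density times tolerance) rather than a bare density, so that
#'   likelihoods remain dimensionally comparable with the atom-carrying
#'   pulsatile class on time-discretised data.
#' @return Vector of per-pair log densities.
#' @export
pair_loglik_none <- function(t1, t2, theta, B, env,
                             control = likelihood_control()) {
  check_pairs(t1, t2)
  stopifnot(theta < 0, B > 0)
  tol <- control$sim_tol %||% control$dt_pde
  g <- ll_grid(env, theta, B, control)
  as.numeric(cpp_pair_loglik_fp(0L, t1, t2, rep(FALSE, length(t1)), theta, 0,
                                B, env$rho, env$tau, env$alpha, g$dt_pde,
                                g$nx, g$x_max, tol, control$density_floor,
                                control$snap_stride))
}

#' Log joint likelihood of an ordered pair under pulsatile coupling
#'
#' Identical to the no-coupling class before the first decision. At `T1`
#' the survivor's conditional density is shifted by `kappa` toward the
#' threshold; the mass pushed past the threshold is the probability atom of
#' a simultaneous departure (`T2 = T1`), and the remaining density
#' propagates under the one-forager drift. Observations flagged
#' simultaneous (or with `t2 - t1` within the simultaneity tolerance)
#' score the atom's log mass; all others score the continuous log density.
#'
#' @inheritParams pair_loglik_none
#' @param kappa Pulse size (>= 0); `kappa = 0` reduces exactly to
#'   [pair_loglik_none()].
#' @param simultaneous Logical flags per pair (default: within tolerance).
#' @export
pair_loglik_pulsatile <- function(t1, t2, theta, kappa, B, env,
                                  simultaneous = NULL,
                                  control = likelihood_control()) {
  check_pairs(t1, t2)
  stopifnot(theta < 0, B > 0)
  if (kappa < 0) stop("pair_loglik_pulsatile: kappa must be non-negative")
  if (is.null(simultaneous)) simultaneous <- rep(FALSE, length(t1))
  tol <- control$sim_tol %||% control$dt_pde
  g <- ll_grid(env, theta, B, control)
  as.numeric(cpp_pair_loglik_fp(1L, t1, t2, simultaneous, theta, kappa, B,
                                env$rho, env$tau, env$alpha, g$dt_pde, g$nx,
                                g$x_max, tol, control$density_floor,
                                control$snap_stride))
}

#' Log joint likelihood of an ordered pair under diffusive coupling
#'
#' Estimated from a seeded common-random-number simulation at the queried
#' parameters: `sim_n` bouts are simulated and a two-dimensional Gaussian
#' product kernel density (rule-of-thumb bandwidths, kernel reflection
#' across `t2 = t1`) is evaluated at the observed pairs. A documented
#' density floor keeps the log likelihood finite in sparse regions.
#' Deterministic given `control$sim_seed`.
#'
#' @inheritParams pair_loglik_pulsatile
#' @export
pair_loglik_diffusive <- function(t1, t2, theta, kappa, B, env,
                                  control = likelihood_control()) {
  check_pairs(t1, t2)
  stopifnot(theta < 0, B > 0)
  if (kappa < 0) stop("pair_loglik_diffusive: kappa must be non-negative")
  tol <- control$sim_tol %||% control$dt_pde
  as.numeric(cpp_pair_loglik_diffusive(t1, t2, theta, kappa, B, env$rho,
                                       env$tau, env$alpha, control$sim_dt,
                                       control$sim_t_max,
                                       as.integer(control$sim_n),
                                       control$sim_seed,
                                       control$density_floor, tol))
}

# dispatch by model class on a pairs data frame; the simultaneity
# tolerance defaults to the generating Euler step recorded on the pairs
loglik_pairs <- function(pairs, params, model_class, env, control) {
  t1 <- pairs$t1
  t2 <- pairs$t2
  if (is.null(control$sim_tol))
    control$sim_tol <- attr(pairs, "gen_dt") %||% control$dt_pde
  switch(model_class,
    none = pair_loglik_none(t1, t2, params[["theta"]], params[["B"]], env,
                            control),
    diffusive = pair_loglik_diffusive(t1, t2, params[["theta"]],
                                      params[["kappa"]], params[["B"]], env,
                                      control),
    pulsatile = pair_loglik_pulsatile(t1, t2, params[["theta"]],
                                      params[["kappa"]], params[["B"]], env,
                                      simultaneous = pairs$simultaneous,
                                      control = control),
    stop("unknown model class: ", model_class))
}
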