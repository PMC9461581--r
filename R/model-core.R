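# Domain types and the resource/drift primitives shared by every model
# variant: the counting function of still-active foragers, the integrated
# depletion exponent, the belief drift, the diffusive coupling increment,
# and the pulse rule with its cascade.

#' Patch environment parameters
#'
#' Bundles the resource and cost parameters of a foraging patch: the initial
#' resource density `rho` (energy/time), the depletion timescale `tau`
#' (time), the foraging/travel cost rate `alpha` (energy/time), and the
#' travel time between patches `travel_time` (time). The model assumes the
#' cost rate is below the initial gain rate (`rho > alpha`), so the belief
#' initially rises before the depleting patch drives it down.
#'
#' @param rho Initial resource density; must exceed `alpha`.
#' @param tau Patch depletion timescale; positive.
#' @param alpha Foraging cost rate; positive gain requires `rho > alpha`.
#' @param travel_time Inter-patch travel time; non-negative.
#' @return An object of class `patch_env`.
#' @examples
#' patch_env(rho = 2, tau = 5, alpha = 1, travel_time = 5)
#' @export
patch_env <- function(rho, tau, alpha, travel_time = 0) {
  stopifnot(is.numeric(rho), is.numeric(tau), is.numeric(alpha),
            is.numeric(travel_time), length(rho) == 1L, length(tau) == 1L)
  if (!(rho > alpha)) stop("patch_env: need rho > alpha (net initial gain)")
  if (!(tau > 0)) stop("patch_env: tau must be positive")
  if (travel_time < 0) stop("patch_env: travel_time must be non-negative")
  structure(list(rho = rho, tau = tau, alpha = alpha,
                 travel_time = travel_time),
            class = "patch_env")
}

#' @export
print.patch_env <- function(x, ...) {
  cat(sprintf("<patch_env> rho = %g, tau = %g, alpha = %g, travel_time = %g\n",
              x$rho, x$tau, x$alpha, x$travel_time))
  invisible(x)
}

#' Per-agent foraging strategy
#'
#' An agent's strategy is its departure threshold `theta` (strictly
#' negative: evidence of depletion accumulates downward) and the coupling
#' strength `kappa` it applies to social input. Under diffusive coupling
#' `kappa` has units 1/time (an attraction rate); under pulsatile coupling
#' it is the size of the belief jump received when a neighbour decides.
#'
#' @param theta Departure threshold, `theta < 0`.
#' @param kappa Coupling strength received by this agent, `kappa >= 0`.
#' @return An object of class `agent_strategy`.
#' @export
agent_strategy <- function(theta, kappa = 0) {
  stopifnot(is.numeric(theta), is.numeric(kappa), length(theta) == 1L)
  if (!(theta < 0)) stop("agent_strategy: theta must be strictly negative")
  if (kappa < 0) stop("agent_strategy: kappa must be non-negative")
  structure(list(theta = theta, kappa = kappa), class = "agent_strategy")
}

#' Group model: coupling mode, strategies, noise and environment
#'
#' @param mode Coupling mode, one of `"none"`, `"diffusive"`, `"pulsatile"`.
#'   With `mode = "none"` all coupling strengths are ignored.
#' @param env A [patch_env()].
#' @param agents List of [agent_strategy()] objects (one per forager), or
#'   `NULL` to build them from `theta`/`kappa`.
#' @param theta,kappa Convenience alternative to `agents`: numeric vectors
#'   (recycled to a common length) of thresholds and coupling strengths.
#' @param noise_scale Diffusion scale `B` shared by all agents; each belief
#'   carries noise `sqrt(2B) dW`.
#' @return An object of class `group_model`.
#' @examples
#' env <- patch_env(2, 5, 1, 5)
#' group_model("diffusive", env, theta = c(-1, -1), kappa = 0.5, noise_scale = 1)
#' @export
group_model <- function(mode = c("none", "diffusive", "pulsatile"), env,
                        agents = NULL, theta = NULL, kappa = 0,
                        noise_scale = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(env, "patch_env"))
  if (is.null(agents)) {
    if (is.null(theta)) stop("group_model: supply `agents` or `theta`")
    n <- max(length(theta), length(kappa))
    theta <- rep_len(theta, n)
    kappa <- rep_len(kappa, n)
    agents <- Map(agent_strategy, theta, kappa)
  }
  if (!length(agents)) stop("group_model: need at least one agent")
  ok <- vapply(agents, inherits, logical(1), what = "agent_strategy")
  if (!all(ok)) stop("group_model: `agents` must be agent_strategy objects")
  if (!(noise_scale > 0)) stop("group_model: noise_scale must be positive")
  structure(list(mode = mode, agents = agents, noise_scale = noise_scale,
                 env = env),
            class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model> mode = %s, N = %d, B = %g\n",
              x$mode, length(x$agents), x$noise_scale))
  cat(sprintf("  theta: %s\n", paste(signif(model_theta(x), 4), collapse = ", ")))
  if (x$mode != "none")
    cat(sprintf("  kappa: %s\n", paste(signif(model_kappa(x), 4), collapse = ", ")))
  print(x$env)
  invisible(x)
}

#' @rdname group_model
#' @param x A `group_model`.
#' @export
model_theta <- function(x) vapply(x$agents, `[[`, numeric(1), "theta")

#' @rdname group_model
#' @export
model_kappa <- function(x) vapply(x$agents, `[[`, numeric(1), "kappa")

#' @rdname group_model
#' @export
model_size <- function(x) length(x$agents)

#' Simulation settings
#'
#' Euler-Maruyama step `dt`, horizon `t_max`, number of independent bouts
#' and the root seed for the per-trial random streams. The default step is
#' small relative to the depletion timescales used throughout (`dt = 0.01`);
#' for diffusive coupling keep `kappa * dt` well below 1.
#'
#' @param dt Time step (> 0).
#' @param t_max Simulation horizon; a bout with an undecided agent at
#'   `t_max` is an error, not silent censoring.
#' @param n_trials Number of independent bouts (>= 1).
#' @param seed Integer root seed; each trial gets its own stream.
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(dt = 0.01, t_max = 150, n_trials = 1000, seed = 1) {
  stopifnot(dt > 0, t_max > 0, n_trials >= 1)
  structure(list(dt = dt, t_max = t_max, n_trials = as.integer(n_trials),
                 seed = as.numeric(seed)),
            class = "sim_settings")
}

#' Counting function of still-foraging agents
#'
#' The number of agents still foraging at time `t`, given the sorted
#' individual decision times. Piecewise constant, non-increasing and taken
#' right-continuous: at exactly a decision time the post-decision count is
#' returned.
#'
#' @param ordered_times Sorted (ascending) decision times recorded so far.
#' @param t Time (scalar or vector), non-negative.
#' @param n Group size.
#' @return Integer count(s) in `0:n`.
#' @export
counting_function <- function(ordered_times, t, n) {
  if (any(t < 0)) stop("counting_function: t must be non-negative")
  if (is.unsorted(ordered_times)) stop("counting_function: times must be sorted")
  vapply(t, function(ti) n - sum(ordered_times <= ti), numeric(1))
}

#' Cumulative depletion exponent
#'
#' The dimensionless integrated depletion
#' \eqn{\Lambda(t) = (1/\tau)\int_0^t \mathcal{N}(s)\,ds}, so the patch
#' resource density is \eqn{\rho e^{-\Lambda(t)}}. Continuous and piecewise
#' linear with slope \eqn{\mathcal{N}(t)/\tau}; in particular the resource
#' density never jumps at a decision time.
#'
#' @inheritParams counting_function
#' @param tau Patch depletion timescale.
#' @export
depletion_exponent <- function(ordered_times, t, tau, n) {
  if (any(t < 0)) stop("depletion_exponent: t must be non-negative")
  if (is.unsorted(ordered_times)) stop("depletion_exponent: times must be sorted")
  one <- function(ti) {
    ev <- ordered_times[ordered_times <= ti]
    starts <- c(0, ev)
    ends <- c(ev, ti)
    counts <- pmax(n - (seq_along(starts) - 1L), 0)
    sum(counts * (ends - starts)) / tau
  }
  vapply(t, one, numeric(1))
}

#' Shared belief drift
#'
#' Drift of every active forager's belief:
#' \eqn{\rho e^{-\Lambda(t)} - \alpha}, where \eqn{\Lambda} is the
#' [depletion_exponent()]. Tends to \eqn{-\alpha} as the patch depletes, so
#' a threshold crossing is eventually certain.
#'
#' @inheritParams counting_function
#' @param env A [patch_env()].
#' @export
patch_drift <- function(ordered_times, t, env, n) {
  lam <- depletion_exponent(ordered_times, t, env$tau, n)
  env$rho * exp(-lam) - env$alpha
}

#' Diffusive coupling increment
#'
#' Per-agent drift increment
#' \eqn{\kappa_i \sum_{j \ne i} [(x_j-\theta_j) - (x_i-\theta_i)]}. Decided
#' agents sit clamped at their threshold and therefore contribute zero
#' distance-to-threshold, pulling undecided neighbours toward departure.
#'
#' @param states Per-agent belief values.
#' @param strategies List of [agent_strategy()] (same length as `states`).
#' @param active Logical mask of still-deciding agents.
#' @return Per-agent coupling increments (zero for decided agents).
#' @export
coupling_drift_diffusive <- function(states, strategies,
                                     active = rep(TRUE, length(states))) {
  stopifnot(length(states) == length(strategies))
  th <- vapply(strategies, `[[`, numeric(1), "theta")
  ka <- vapply(strategies, `[[`, numeric(1), "kappa")
  g <- ifelse(active, states - th, 0)
  n <- length(states)
  incr <- ka * (sum(g) - n * g)
  incr[!active] <- 0
  incr
}

#' Apply a decision pulse and resolve its cascade
#'
#' When an agent reaches threshold under pulsatile coupling, every
#' undecided agent's belief jumps down by its own coupling strength
#' `kappa_i`. Any agent pushed to or past its threshold decides at the same
#' instant and recursively emits its own pulse. Each cascade step strictly
#' shrinks the undecided set, so termination is guaranteed.
#'
#' @param states Per-agent belief values at the decision instant.
#' @param strategies List of [agent_strategy()].
#' @param decider_index Index of the agent that has just reached threshold.
#' @param decided Logical vector of agents already decided *before* this
#'   crossing (default: none).
#' @return A list with `states` (decided agents clamped at threshold),
#'   `cascade` (indices newly decided by pulses, in cascade order) and the
#'   updated `decided` mask.
#' @export
apply_pulse <- function(states, strategies, decider_index, decided = NULL) {
  n <- length(states)
  stopifnot(length(strategies) == n)
  th <- vapply(strategies, `[[`, numeric(1), "theta")
  ka <- vapply(strategies, `[[`, numeric(1), "kappa")
  if (is.null(decided)) decided <- rep(FALSE, n)
  if (decided[decider_index])
    stop("apply_pulse: decider is already decided")
  decided[decider_index] <- TRUE
  states[decider_index] <- th[decider_index]
  cascade <- integer(0)
  queue <- decider_index
  qi <- 1L
  while (qi <= length(queue)) {
    qi <- qi + 1L # each queued decider emits one pulse
    for (j in seq_len(n)) {
      if (!decided[j]) {
        states[j] <- states[j] - ka[j]
        if (states[j] <= th[j]) {
          decided[j] <- TRUE
          states[j] <- th[j]
          cascade <- c(cascade, j)
          queue <- c(queue, j)
        }
      }
    }
  }
  list(states = states, cascade = cascade, decided = decided)
}

#' Departure record of one foraging bout
#'
#' @param times Per-agent decision times (agent order).
#' @param decider_order Agent indices in decision order.
#' @param simultaneous Per-agent flag: decision triggered instantaneously
#'   by a pulse.
#' @return An object of class `departure_record` with sorted
#'   `ordered_times` and `group_time = max(times)`.
#' @export
departure_record <- function(times, decider_order = order(times),
                             simultaneous = rep(FALSE, length(times))) {
  stopifnot(length(times) >= 1, !anyNA(times))
  structure(list(times = times,
                 ordered_times = times[decider_order],
                 decider_order = decider_order,
                 simultaneous = simultaneous,
                 group_time = max(times)),
            class = "departure_record")
}

#' @export
print.departure_record <- function(x, ...) {
  cat(sprintf("<departure_record> N = %d, group_time = %.4g\n",
              length(x$times), x$group_time))
  cat("  ordered times:", paste(signif(x$ordered_times, 5), collapse = ", "), "\n")
  if (any(x$simultaneous))
    cat("  pulse-triggered agents:", which(x$simultaneous), "\n")
  invisible(x)
}
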