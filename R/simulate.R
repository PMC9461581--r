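# Euler-Maruyama Monte Carlo engine: single bouts (optionally with the
# full belief trajectory), dataset generation for inference, and the
# empirical group departure-time distribution.

mode_code <- function(mode) match(mode, c("none", "diffusive", "pulsatile")) - 1L

#' Simulate one foraging bout
#'
#' All beliefs start at 0 and evolve by Euler-Maruyama steps
#' `x_i <- x_i + (drift + coupling) dt + sqrt(2 B dt) z_i` until every
#' agent has crossed its threshold. Crossings are detected at step
#' resolution and recorded at the step's end time; decided agents clamp at
#' their threshold; in pulsatile mode a crossing delivers its pulses (and
#' any cascade) before the next step; the depletion drift updates after
#' each decision. One normal deviate is drawn per agent per step whether or
#' not the agent is still active, so runs with `kappa = 0` reproduce
#' `mode = "none"` exactly at a matched seed.
#'
#' @param model A [group_model()].
#' @param settings A [sim_settings()]; `n_trials` is ignored (single bout).
#' @param record_trajectory If `TRUE` also return the belief trajectory.
#' @param trajectory_stride Record every so-many steps.
#' @return A [departure_record()]; with `record_trajectory = TRUE` the
#'   record carries a `trajectory` element (class `forage_trajectory`) with
#'   the time grid, per-agent states and the active-forager count.
#' @export
simulate_bout <- function(model, settings = sim_settings(),
                          record_trajectory = FALSE, trajectory_stride = 1L) {
  stopifnot(inherits(model, "group_model"), inherits(settings, "sim_settings"))
  th <- model_theta(model)
  ka <- model_kappa(model)
  if (record_trajectory) {
    res <- cpp_simulate_trajectory(mode_code(model$mode), th, ka,
                                   model$noise_scale, model$env$rho,
                                   model$env$tau, model$env$alpha,
                                   settings$dt, settings$t_max,
                                   settings$seed, as.integer(trajectory_stride))
    if (res$truncated)
      stop("simulate_bout: agent(s) undecided at t_max; increase t_max")
    rec <- departure_record(res$T, order(res$T, seq_along(res$T)),
                            res$simultaneous == 1L)
    rec$trajectory <- structure(list(times = res$times, states = res$states,
                                     n_active = res$n_active),
                                class = "forage_trajectory")
    return(rec)
  }
  res <- cpp_simulate_bouts(mode_code(model$mode), th, ka, model$noise_scale,
                            model$env$rho, model$env$tau, model$env$alpha,
                            settings$dt, settings$t_max, 1L, settings$seed)
  if (res$n_truncated > 0)
    stop("simulate_bout: agent(s) undecided at t_max; increase t_max")
  times <- as.numeric(res$times[1, ])
  departure_record(times, order(times, seq_along(times)),
                   res$simultaneous[1, ] == 1L)
}

#' Simulate a departure-time dataset
#'
#' Runs `settings$n_trials` independent bouts (one random stream per trial,
#' spawned from the root seed, so results do not depend on execution
#' order). Returns the long-format table used throughout inference.
#'
#' @inheritParams simulate_bout
#' @return A `departure_dataset`: a data frame with columns `trial`,
#'   `agent`, `decision_time`, `decision_rank`, `simultaneous`, carrying
#'   the generating model, settings and seed as attributes.
#' @examples
#' env <- patch_env(2, 5, 1, 5)
#' m <- group_model("pulsatile", env, theta = c(-1, -1), kappa = 2,
#'                  noise_scale = 1)
#' d <- simulate_dataset(m, sim_settings(n_trials = 20, seed = 42))
#' head(d)
#' @export
simulate_dataset <- function(model, settings = sim_settings()) {
  stopifnot(inherits(model, "group_model"), inherits(settings, "sim_settings"))
  th <- model_theta(model)
  ka <- model_kappa(model)
  n <- model_size(model)
  res <- cpp_simulate_bouts(mode_code(model$mode), th, ka, model$noise_scale,
                            model$env$rho, model$env$tau, model$env$alpha,
                            settings$dt, settings$t_max, settings$n_trials,
                            settings$seed)
  if (res$n_truncated > 0)
    stop(sprintf("simulate_dataset: %d bout(s) with undecided agents at t_max = %g; increase t_max",
                 res$n_truncated, settings$t_max))
  times <- res$times
  ranks <- t(apply(times, 1, function(r) rank(r, ties.method = "first")))
  if (n == 1) ranks <- matrix(1, nrow = settings$n_trials, ncol = 1)
  out <- data.frame(
    trial = rep(seq_len(settings$n_trials), times = n),
    agent = rep(seq_len(n), each = settings$n_trials),
    decision_time = as.vector(times),
    decision_rank = as.vector(ranks),
    simultaneous = as.vector(res$simultaneous == 1L)
  )
  out <- out[order(out$trial, out$agent), ]
  rownames(out) <- NULL
  class(out) <- c("departure_dataset", "data.frame")
  attr(out, "model") <- model
  attr(out, "settings") <- settings
  out
}

#' Ordered departure-time pairs of a two-agent dataset
#'
#' @param dataset A `departure_dataset` (two agents) or a data frame with
#'   columns `t1`, `t2` and optionally `simultaneous`.
#' @return Data frame with `t1 <= t2` per trial and a `simultaneous` flag
#'   (pulse-triggered second decision, or exactly equal recorded times).
#' @export
departure_pairs <- function(dataset) {
  if (!is.null(dataset$t1) && !is.null(dataset$t2)) {
    out <- data.frame(t1 = dataset$t1, t2 = dataset$t2,
                      simultaneous = dataset$simultaneous %||%
                        (dataset$t2 - dataset$t1 <= 0))
    return(out)
  }
  stopifnot(inherits(dataset, "data.frame"),
            all(c("trial", "decision_time") %in% names(dataset)))
  sp <- split(dataset, dataset$trial)
  t1 <- vapply(sp, function(d) min(d$decision_time), numeric(1))
  t2 <- vapply(sp, function(d) max(d$decision_time), numeric(1))
  sim <- vapply(sp, function(d) any(d$simultaneous) || diff(range(d$decision_time)) <= 0,
                logical(1))
  out <- data.frame(t1 = unname(t1), t2 = unname(t2), simultaneous = unname(sim))
  attr(out, "gen_dt") <- attr(dataset, "settings")$dt
  out
}

#' Empirical distribution of group departure times
#'
#' Normalised histogram (integrates to one) of the per-bout group departure
#' time (the last individual decision), plus its mean.
#'
#' @param dataset A `departure_dataset`.
#' @param bin_width Histogram bin width.
#' @return List with `breaks`, `mids`, `density`, `mean_time` and the raw
#'   `group_times`, class `departure_histogram`.
#' @export
empirical_departure_distribution <- function(dataset, bin_width = 0.5) {
  stopifnot(nrow(dataset) > 0, bin_width > 0)
  gt <- tapply(dataset$decision_time, dataset$trial, max)
  gt <- as.numeric(gt)
  breaks <- seq(0, max(gt) + bin_width, by = bin_width)
  h <- graphics::hist(gt, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, mids = h$mids, density = h$density,
                 mean_time = mean(gt), group_times = gt),
            class = "departure_histogram")
}
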