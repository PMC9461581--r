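# 1D time-inhomogeneous Fokker-Planck machinery: absorbing threshold at
# theta, reflecting upper wall, Scharfetter-Gummel flux discretisation with
# Rannacher-started Crank-Nicolson stepping (see the methods vignette).
# The first-passage density is the per-step absorbed probability mass,
# which the flux-form scheme conserves exactly.

#' Spatial/temporal grid for the Fokker-Planck solver
#'
#' `x_max` and `nx` default to `NULL`, in which case they are chosen
#' adaptively from the noise-free belief excursion plus a diffusion-length
#' pad (see [solve_fp_1d()] callers); `dt_pde` is the time step.
#'
#' @param x_max Upper (reflecting) truncation boundary, or `NULL` for auto.
#' @param nx Number of spatial nodes, or `NULL` for auto.
#' @param dt_pde Time step of the solver.
#' @export
grid_spec <- function(x_max = NULL, nx = NULL, dt_pde = 0.02) {
  stopifnot(dt_pde > 0)
  structure(list(x_max = x_max, nx = nx, dt_pde = dt_pde), class = "grid_spec")
}

# Adaptive truncation: cover the noise-free excursion peak of a single
# forager plus a multiple of the diffusion length over the characteristic
# crossing time. Returns completed grid_spec.
auto_grid <- function(env, theta, D, grid = grid_spec()) {
  if (!is.null(grid$x_max) && !is.null(grid$nx)) return(grid)
  rho <- env$rho; tau <- env$tau; alpha <- env$alpha
  xfree <- function(t) rho * tau * (1 - exp(-t / tau)) - alpha * t
  t_peak <- tau * log(rho / alpha)
  x_peak <- max(xfree(t_peak), 0)
  # upward spread during the rising phase plus the stationary-like
  # excursion against the eventual -alpha drift; tails beyond this are
  # exponentially suppressed
  pad <- max(1.5, 2.5 * sqrt(2 * D * t_peak) + 1.5 * D / alpha)
  if (is.null(grid$x_max)) grid$x_max <- x_peak + pad
  if (is.null(grid$nx)) {
    width <- grid$x_max - theta
    grid$nx <- as.integer(min(260, max(90, ceiling(width / 0.12))))
  }
  grid
}

#' First-passage-time density on a time grid
#'
#' Container for a first-passage density: a time grid, the density values,
#' the survival function, and an optional discrete atom (used for the
#' probability of pulse-triggered simultaneous departures).
#'
#' @param time Increasing time grid (step midpoints of the solver).
#' @param density Non-negative density values (1/time).
#' @param survival Survival probabilities at the same times.
#' @param atom_mass Probability mass at `atom_time` (default none).
#' @param atom_time Location of the atom.
#' @return An object of class `fpt_density`. The attribute `captured` holds
#'   the probability mass accounted for on the grid (continuous + atom).
#' @export
fpt_density <- function(time, density, survival, atom_mass = 0,
                        atom_time = NA_real_) {
  stopifnot(length(time) == length(density), length(time) == length(survival))
  density <- pmax(density, 0)
  dt <- diff(time)
  captured <- sum(density[-1] * dt) + density[1] * time[1] * 2 + atom_mass
  structure(list(time = time, density = density, survival = survival,
                 atom_mass = atom_mass, atom_time = atom_time),
            captured = min(captured, 1), class = "fpt_density")
}

#' @export
print.fpt_density <- function(x, ...) {
  cat(sprintf("<fpt_density> %d time points on [%.3g, %.3g], captured mass %.4f",
              length(x$time), min(x$time), max(x$time), attr(x, "captured")))
  if (x$atom_mass > 0)
    cat(sprintf(", atom %.4f at t = %.3g", x$atom_mass, x$atom_time))
  cat("\n")
  invisible(x)
}

#' Mean of a first-passage density
#'
#' Mean conditional on capture within the grid (the captured mass is
#' reported by `attr(x, "captured")`).
#' @param x An [fpt_density()].
#' @export
fpt_mean <- function(x) {
  dt <- c(x$time[1] * 2, diff(x$time))
  m <- sum(x$time * x$density * dt) +
    (if (x$atom_mass > 0) x$atom_mass * x$atom_time else 0)
  cont <- sum(x$density * dt) + x$atom_mass
  m / cont
}

#' Cumulative distribution of a first-passage density
#'
#' Returns a function `F(t)` interpolating the captured cumulative mass;
#' used for Kolmogorov-Smirnov comparisons against simulation.
#' @param x An [fpt_density()].
#' @export
fpt_cdf <- function(x) {
  dt <- c(x$time[1] * 2, diff(x$time))
  cum <- cumsum(x$density * dt)
  if (x$atom_mass > 0) cum <- cum + x$atom_mass * (x$time >= x$atom_time)
  tt <- c(0, x$time)
  cc <- c(0, pmin(cum, 1))
  function(t) approx(tt, cc, xout = t, rule = 2)$y
}

#' Solve a 1D Fokker-Planck first-passage problem
#'
#' Solves \eqn{\partial_t p = -\mu(t)\partial_x p + D \partial_x^2 p} on
#' `(theta, x_max)` with an absorbing boundary at the threshold `theta` and
#' a reflecting upper wall, for a drift that depends on time only (the
#' depletion drift is shared by all foragers). The first-passage density is
#' the probability flux through `theta`, read off the per-step absorbed
#' mass so that interior + absorbed mass is conserved to machine precision.
#'
#' @param drift_fn Function of time returning the drift.
#' @param diffusion Diffusion coefficient `D` (the SDE noise is
#'   `sqrt(2D) dW`).
#' @param theta Absorbing threshold (< starting point).
#' @param t_span Length-2 numeric: start and end times.
#' @param grid A [grid_spec()]; `x_max`/`nx` must be set (use the limit-case
#'   wrappers for automatic grids).
#' @param init Either `NULL` (point mass at `init_x`) or a density vector
#'   of length `nx` on the interior nodes.
#' @param init_x Starting point for the default point-mass initial
#'   condition.
#' @param mass_tol If the captured mass at the end of `t_span` is below
#'   `1 - mass_tol` a truncation warning reports the captured mass.
#' @return A list with the `fpt` ([fpt_density()]), the final interior
#'   density `p_final`, and the node spacing `dx`.
#' @examples
#' # constant net drift toward the threshold: inverse-Gaussian passage times
#' sol <- solve_fp_1d(function(t) -1, diffusion = 0.5, theta = -1,
#'                    t_span = c(0, 8),
#'                    grid = grid_spec(x_max = 4, nx = 200, dt_pde = 0.01))
#' attr(sol$fpt, "captured")
#' @export
solve_fp_1d <- function(drift_fn, diffusion, theta, t_span,
                        grid = grid_spec(), init = NULL, init_x = 0,
                        mass_tol = 1e-3) {
  stopifnot(diffusion > 0, theta < init_x, length(t_span) == 2)
  if (is.null(grid$x_max) || is.null(grid$nx))
    stop("solve_fp_1d: grid$x_max and grid$nx must be set")
  dt <- grid$dt_pde
  nt <- ceiling((t_span[2] - t_span[1]) / dt - 1e-9)
  tm <- t_span[1] + (seq_len(nt) - 0.5) * dt
  mu <- vapply(tm, drift_fn, numeric(1))
  p0 <- if (is.null(init)) numeric(0) else init
  res <- cpp_fp_solve_mu(mu, diffusion, theta, grid$x_max, grid$nx, dt, p0, init_x)
  S0 <- if (is.null(init)) 1 else sum(init) * res$dx
  fpt <- fpt_density(time = tm, density = res$f, survival = res$S)
  # interior + absorbed must account for the initial mass (no leakage)
  if ((res$S[nt] + attr(fpt, "captured")) < S0 - mass_tol)
    warning(sprintf("solve_fp_1d: mass accounting gap %.4g (interior %.4f + absorbed %.4f)",
                    S0 - res$S[nt] - attr(fpt, "captured"), res$S[nt],
                    attr(fpt, "captured")))
  list(fpt = fpt, p_final = res$p_final, dx = res$dx)
}
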