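# shared fixtures: the reference patch environment used across the study
# (rho = 2, tau = 5, alpha = 1, travel time 5) and its high-food variant
ref_env <- function() patch_env(rho = 2, tau = 5, alpha = 1, travel_time = 5)
rich_env <- function() patch_env(rho = 6, tau = 5, alpha = 1, travel_time = 5)

# symmetric two-forager model shortcut
two_agent <- function(mode, theta, kappa = 0, B = 1, env = ref_env()) {
  group_model(mode, env, theta = rep(theta, 2), kappa = kappa,
              noise_scale = B)
}

# closed-form inverse-Gaussian first-passage density for constant net
# drift mu toward a threshold at distance a, diffusion coefficient D
inverse_gaussian_fpt <- function(t, a, mu, D) {
  lam <- a^2 / (2 * D)
  m <- a / mu
  sqrt(lam / (2 * pi * t^3)) * exp(-lam * (t - m)^2 / (2 * m^2 * t))
}

# Kolmogorov-Smirnov distance between samples and a cdf function
ks_dist <- function(samples, cdf_fn) {
  s <- sort(samples)
  n <- length(s)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  th <- cdf_fn(s)
  max(abs(emp_hi - th), abs(emp_lo - th))
}
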