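# socforage

Foraging animals that move as a cohesive group face a coupled decision
problem: each individual accumulates noisy evidence that the current food
patch is depleting, but nobody leaves until everyone has decided, so the
group pays for every poorly timed individual decision. `socforage` is an R
package for modelling, simulating and fitting this process. It is aimed at
behavioural ecologists and computational neuroscientists who want
mechanistic, fittable models of collective patch departure — e.g. for
departure-time data from pairs of foraging primates or birds.

## The model

Each forager `i` in a group of `N` carries a belief `x_i(t)` (its
motivation to keep foraging), starting at 0 and evolving as a
drift–diffusion process

    dx_i = [ rho * exp(-Lambda(t)) - alpha + coupling_i ] dt + sqrt(2B) dW_i

where `rho` is the initial resource density, `alpha` the foraging cost
rate, `B` the belief noise scale, and
`Lambda(t) = (1/tau) * integral of N(t)` the cumulative depletion driven by
the number `N(t)` of still-foraging animals (timescale `tau`). Forager `i`
stops at the first passage of `x_i` below its negative threshold
`theta_i`; the group departs at `T_N = max(T_i)`. Two communication modes
couple the beliefs:

* **diffusive** — continuous attraction
  `kappa_i * sum_j [(x_j - theta_j) - (x_i - theta_i)]` throughout
  deliberation;
* **pulsatile** — a jump of size `kappa_i` toward threshold delivered to
  every undecided forager at the moment a neighbour decides (possibly
  cascading into simultaneous group departure).

Strategy efficiency is the reward rate

    RR = ( <r_N> - alpha * (T_I + <T_N>) ) / (T_I + <T_N>)

with `r_N = rho * tau * (1 - exp(-Lambda(T_N)))` the food consumed by the
group and `T_I` the travel time between patches. The package also inverts
the model: given ordered departure-time pairs it computes exact
(Fokker–Planck) or simulation-based likelihoods per coupling class, MAP
parameter estimates under uniform priors, and Monte Carlo Bayes factors to
identify the communication mode.

## Worked example

Simulate a pulsatile pair, score its strategy, and recover the generating
parameters from its own departure times:

```r
library(socforage)

env   <- patch_env(rho = 2, tau = 5, alpha = 1, travel_time = 5)
model <- group_model("pulsatile", env, theta = c(-1, -1), kappa = 1.5,
                     noise_scale = 1)

simulate_bout(model, sim_settings(seed = 42))
#> <departure_record> N = 2, group_time = 0.19
#>   ordered times: 0.19, 0.19
#>   pulse-triggered agents: 1

evaluate_strategy(model, sim_settings(n_trials = 2000, seed = 42))
#> <strategy_eval> RR = -0.4146 (se 0.0045), mean reward 5.413, mean group time 4.247 (n = 2000)

ds  <- simulate_dataset(model, sim_settings(n_trials = 200, seed = 42))
fit <- map_estimate(departure_pairs(ds), "pulsatile", prior_box(), env)
fit
#> <map_fit> class = pulsatile, log posterior = -688.380
#>  theta  kappa      B
#> -1.019  1.575  1.075

log_bayes_factor(departure_pairs(ds), "pulsatile", "none", prior_box(), env,
                 n_prior_samples = 16, seed = 1)
#> [1] 349.9939
```

Reading the output: in the seed-42 bout the first decider's pulse
instantly triggered its partner (`group_time = 0.19`, both times equal).
Averaged over 2000 bouts this strategy loses energy at rate 0.41 per unit
time in this poor patch (`rho = 2` with travel time 5 makes even good
strategies near break-even). The MAP fit recovers the generating
parameters `(theta, kappa, B) = (-1, 1.5, 1)` to within the search
resolution, and the strongly positive log Bayes factor correctly
attributes the data to pulsatile rather than uncoupled foraging — tied
departure pairs are the signature of pulse-driven cascades.

Limit-case analysis and strategy optimisation:

```r
compare_limit_cases(env, theta_grid = seq(-3, -0.1, by = 0.1), B = 1,
                    settings = sim_settings(n_trials = 10000, seed = 1))
# reward rates of no coupling vs perfect diffusive / pulsatile coupling
sweep_symmetric("diffusive", patch_env(4, 5, 1, 5),
                theta_grid = seq(-4, -0.25, by = 0.25),
                kappa_grid = c(0, 0.5, 1, 2, 4), B = 1,
                settings = sim_settings(n_trials = 5000, seed = 1))
```

A thin shell entry point is installed at `inst/scripts/socforage`
(`simulate`, `fit`, `experiment` sub-commands over the same functions).

## Package tour

| Area | Functions |
| --- | --- |
| Model types | `patch_env`, `agent_strategy`, `group_model`, `sim_settings` |
| Dynamics primitives | `counting_function`, `depletion_exponent`, `patch_drift`, `coupling_drift_diffusive`, `apply_pulse` |
| Simulation | `simulate_bout`, `simulate_dataset`, `departure_pairs`, `empirical_departure_distribution` |
| Limits & first passage | `ou_half_difference_variance`, `d_infinity_fpt`, `p_infinity_group_fpt`, `nc_group_fpt`, `solve_fp_1d` |
| Reward | `total_food_consumed`, `reward_rate`, `evaluate_strategy`, `compare_limit_cases`, `sweep_symmetric`, `optimize_partner` |
| Inference | `prior_box`, `pair_loglik_*`, `log_posterior`, `map_estimate`, `relative_error`, `log_marginal_likelihood`, `log_bayes_factor`, `confusion_experiment`, `parameter_recovery_experiment` |
| I/O & pipelines | `write_group_config`, `write_departures`, `write_fpt_density`, `cli_simulate`, `cli_fit`, `cli_experiment` |

The methods vignette (`vignettes/social-foraging-methods.Rmd`) documents
the model assumptions, the numerical schemes and their error behaviour,
and every default parameter choice.
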