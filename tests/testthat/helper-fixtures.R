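# Shared fixtures: everything is generated in code at test time.

# Schematic parameter sets for the three forms (growth factor 3, quoted
# limit 40 so k2 = 0.075, damped competition coefficient 0.5).
fig_params <- list(
  scramble = c(r = 3, K = 40),
  contest = c(k1 = 3, k2 = 0.075),
  damped_increase = c(k1 = 3, k2 = 0.075, c = 0.5)
)

# A driver-free environment: one sample per 1-Myr bin, zero anomaly,
# constant package count.
flat_env <- function(n, P = 20, O = 0) {
  data.frame(age = rev(seq_len(n)) - 0.5, temperature = 0,
             package_count = P, package_originations = O)
}

# Simulate a richness trajectory under `form` and wrap it as a binned series
# ready for fitting.
sim_binned <- function(form, params = fig_params[[form]], n = 60, x0 = 1,
                       noise_sd = 1, env_seed = 1, traj_seed = 1,
                       spec = model_spec(form)) {
  env <- simulate_environment(simulation_config(n_steps = n, seed = env_seed))
  x <- simulate_richness(spec, params, x0, env, noise_sd = noise_sd,
                         seed = traj_seed)
  as_binned_series(x, env)
}

# Deterministic free iteration of the one-step map (no noise, no drivers).
iterate_map <- function(spec, params, x0, n_steps, T = 0, P = 20, O = 0) {
  x <- numeric(n_steps + 1)
  x[1] <- x0
  for (i in seq_len(n_steps))
    x[i + 1] <- step_richness(spec, params, x[i], T = T, P = P, O = O)
  x
}

# Exhaustive grid-search RSS minimum for the 2-parameter fixed forms;
# independent of the Levenberg-Marquardt path.
grid_min_rss <- function(form, tr, n_grid = 200) {
  x <- tr$x; y <- tr$x_next
  if (form == "scramble") {
    p1 <- seq(0.01, 6, length.out = n_grid)          # r
    p2 <- seq(1, 10 * max(x), length.out = n_grid)   # K
    pred <- function(a, b) x * exp(a * (1 - x / b))
  } else {
    p1 <- seq(0.01, 6, length.out = n_grid)          # k1
    p2 <- seq(1e-4, 0.5, length.out = n_grid)        # k2
    pred <- function(a, b) a * x / (1 + b * x)
  }
  best <- Inf
  for (a in p1) {
    preds <- vapply(p2, function(b) pred(a, b), numeric(length(x)))
    rss <- colSums((y - preds)^2)
    best <- min(best, rss)
  }
  best
}

# The 7-model comparison set used in power checks: the three fixed biotic
# forms plus the four abiotic nulls.
fixed_plus_nulls <- function() {
  c(build_model_set(rate_driver_sets = list(character()),
                    limit_driver_sets = list(character()),
                    include_abiotic = FALSE),
    build_model_set(forms = character(0), include_abiotic = TRUE))
}
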