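#' Configuration for the synthetic-data generators
#'
#' Bundles everything [simulate_environment()] and [simulate_richness()] need
#' to emulate the statistical structure of the real inputs: a fossil richness
#' trajectory, a deep-ocean temperature anomaly series, and Atlantic
#' macrostratigraphic package counts and originations.
#'
#' @param n_steps number of time steps (>= 3).
#' @param step_length Myr per step (> 0).
#' @param seed integer RNG seed.
#' @param model a `model_spec` generating the richness trajectory.
#' @param params named parameters for `model`.
#' @param x0 initial richness (>= 0).
#' @param noise_sd sd of additive Gaussian observation noise on richness
#'   (>= 0; the least-squares error model).
#' @param temp_params named list: `trend_amplitude` (degC, slow cosine trend
#'   across the span), `reversion` (mean-reversion strength per step, in
#'   [0, 1]), `innovation_sd` (degC per step).
#' @param package_params named list: `mean_count` (mean package count),
#'   `dispersion` (variance/mean ratio of counts; 1 = Poisson, > 1 negative
#'   binomial), `mean_originations` (mean package originations per step, Poisson).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_steps = 65L,
                              step_length = 1,
                              seed = 1L,
                              model = model_spec("contest"),
                              params = c(k1 = 3, k2 = 0.075),
                              x0 = 1,
                              noise_sd = 1,
                              temp_params = list(trend_amplitude = 4,
                                                 reversion = 0.2,
                                                 innovation_sd = 0.5),
                              package_params = list(mean_count = 20,
                                                    dispersion = 1,
                                                    mean_originations = 1)) {
  if (!is.numeric(n_steps) || n_steps < 3)
    stop("invalid config field n_steps: must be >= 3", call. = FALSE)
  if (!is.numeric(step_length) || step_length <= 0)
    stop("invalid config field step_length: must be > 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid config field noise_sd: must be >= 0", call. = FALSE)
  if (!is.numeric(x0) || x0 < 0)
    stop("invalid config field x0: must be >= 0", call. = FALSE)
  tp <- temp_params
  if (!all(c("trend_amplitude", "reversion", "innovation_sd") %in% names(tp)) ||
      tp$innovation_sd < 0 || tp$reversion < 0 || tp$reversion > 1)
    stop("invalid config field temp_params", call. = FALSE)
  pp <- package_params
  if (!all(c("mean_count", "dispersion", "mean_originations") %in% names(pp)) ||
      any(unlist(pp) < 0) || pp$dispersion < 1)
    stop("invalid config field package_params: all must be >= 0, dispersion >= 1",
         call. = FALSE)
  stopifnot(inherits(model, "model_spec"))
  structure(
    list(n_steps = as.integer(n_steps), step_length = step_length,
         seed = as.integer(seed), model = model, params = params, x0 = x0,
         noise_sd = noise_sd, temp_params = tp, package_params = pp),
    class = "simulation_config"
  )
}

#' Simulate an environment series
#'
#' Temperature is a mean-reverting Gaussian walk plus an optional slow cosine
#' trend across the span, then mean-centred (so the anomalies sum to zero to
#' numerical precision). Package counts are Poisson (or negative binomial
#' when `dispersion > 1`) around the configured mean; package originations
#' are Poisson. Samples sit at step midpoints, oldest first, so that binning
#' at the generating step length sees exactly one sample per bin.
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `age` (Ma, descending), `temperature`
#'   (mean-centred degC), `package_count`, `package_originations`.
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_steps
  span <- n * config$step_length
  age <- (seq_len(n) - 0.5) * config$step_length
  age <- rev(age)  # oldest first
  tp <- config$temp_params
  pp <- config$package_params
  withr::with_seed(config$seed, {
    walk <- numeric(n)
    innov <- stats::rnorm(n, 0, tp$innovation_sd)
    for (i in seq_len(n))
      walk[i] <- (1 - tp$reversion) * (if (i == 1) 0 else walk[i - 1]) + innov[i]
    temperature <- walk + tp$trend_amplitude * cos(pi * age / span)
    temperature <- temperature - mean(temperature)
    package_count <- if (pp$dispersion > 1) {
      stats::rnbinom(n, mu = pp$mean_count,
                     size = pp$mean_count / (pp$dispersion - 1))
    } else {
      stats::rpois(n, pp$mean_count)
    }
    package_originations <- stats::rpois(n, pp$mean_originations)
  })
  data.frame(age = age, temperature = temperature,
             package_count = package_count,
             package_originations = package_originations)
}

#' Simulate a richness trajectory under a competition model
#'
#' Iterates the exact one-step map of [step_richness()] along the environment
#' series (one step per environment sample, oldest first), adding Gaussian
#' observation noise per step and truncating at zero from below. With
#' `noise_sd = 0` the deterministic trajectory is reproduced exactly.
#'
#' @param spec a `model_spec`.
#' @param params named parameters.
#' @param x0 initial richness (>= 0).
#' @param env environment series (drivers per step).
#' @param noise_sd sd of additive Gaussian noise (>= 0).
#' @param seed integer seed.
#' @return numeric vector of length `nrow(env) + 1`: `x0` followed by one
#'   value per step, oldest first.
#' @export
simulate_richness <- function(spec, params, x0, env, noise_sd = 0, seed = 1L) {
  check_params(spec, params)
  if (!is.numeric(x0) || x0 < 0) stop("x0 must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  env <- as_environment(env)
  n <- nrow(env)
  x <- numeric(n + 1L)
  x[1] <- x0
  withr::with_seed(as.integer(seed), {
    eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    for (i in seq_len(n)) {
      pred <- step_richness(spec, params, x[i],
                            T = env$temperature[i],
                            P = env$package_count[i],
                            O = env$package_originations[i])
      x[i + 1L] <- max(0, pred + if (noise_sd > 0) eps[i] else 0)
    }
  })
  x
}

#' Simulate species durations by diversity-dependent birth-death
#'
#' A continuous-time birth-death process starting from a single founder
#' lineage at age `span`, with per-lineage speciation rate
#' `base_speciation_rate * max(0, 1 - N/limit)` (linear diversity dependence
#' on speciation only) and constant per-lineage extinction rate. Lineages
#' alive at age 0 are flagged extant. A realisation in which the clade dies
#' out before half the span has elapsed is discarded and re-drawn from a new
#' stream, up to `max_attempts` times.
#'
#' @param seed integer seed.
#' @param base_speciation_rate per-lineage per-Myr (>= 0).
#' @param base_extinction_rate per-lineage per-Myr (>= 0).
#' @param limit richness at which speciation shuts off (> 0).
#' @param span clade age in Myr (> 0).
#' @param max_attempts retry cap for early total extinction.
#' @return data.frame with columns `species`, `origin_age`, `extinction_age`
#'   (Ma; extant lineages get 0), `extant` (logical).
#' @export
simulate_durations <- function(seed, base_speciation_rate, base_extinction_rate,
                               limit, span, max_attempts = 100L) {
  stopifnot(base_speciation_rate >= 0, base_extinction_rate >= 0,
            limit > 0, span > 0, max_attempts >= 1)
  for (attempt in seq_len(max_attempts)) {
    out <- withr::with_seed(as.integer(seed) + (attempt - 1L) * 7919L,
                            bd_realisation(base_speciation_rate,
                                           base_extinction_rate, limit, span))
    if (!out$early_extinct) {
      d <- out$durations
      return(d[order(-d$origin_age, d$species), , drop = FALSE])
    }
  }
  stop("clade went extinct before span/2 in all ", max_attempts, " attempts",
       call. = FALSE)
}

bd_realisation <- function(lambda0, mu, limit, span) {
  origin <- span          # birth times recorded as ages
  death <- NA_real_
  alive <- 1L             # indices of living lineages
  t <- 0
  repeat {
    n <- length(alive)
    if (n == 0L) break
    lam <- lambda0 * max(0, 1 - n / limit)
    total <- n * (lam + mu)
    if (total <= 0) break
    t <- t + stats::rexp(1, total)
    if (t >= span) break
    who <- alive[sample.int(n, 1L)]
    if (stats::runif(1) < lam / (lam + mu)) {
      origin <- c(origin, span - t)
      death <- c(death, NA_real_)
      alive <- c(alive, length(origin))
    } else {
      death[who] <- span - t
      alive <- setdiff(alive, who)
    }
  }
  extant <- is.na(death)
  death[extant] <- 0
  durations <- data.frame(
    species = paste0("sp", seq_along(origin)),
    origin_age = origin,
    extinction_age = death,
    extant = extant
  )
  list(durations = durations,
       early_extinct = length(alive) == 0L && t < span / 2)
}
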