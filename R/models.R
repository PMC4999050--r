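#' Define a competition model specification
#'
#' A model spec pairs one of the discrete-time functional forms with the
#' environmental drivers allowed to act on the per-lineage diversification
#' rate and on the upper ecological limit (or density coefficient).
#'
#' Forms:
#' \describe{
#'   \item{scramble}{Ricker map \eqn{x_{t+1} = x_t \exp(r (1 - x_t/K))};
#'     overcompensatory, produces overshoot-and-crash dynamics.}
#'   \item{contest}{Beverton-Holt map \eqn{x_{t+1} = k_1 x_t / (1 + k_2 x_t)};
#'     compensatory, non-decreasing approach to a finite limit.}
#'   \item{damped_increase}{Hassell map
#'     \eqn{x_{t+1} = k_1 x_t / (1 + k_2 x_t)^c}; \eqn{c = 1} recovers
#'     contest, \eqn{c > 1} implies scramble-like overcompensation,
#'     \eqn{0 < c < 1} a damped increase.}
#'   \item{abiotic}{No-competition null \eqn{x_{t+1} = x_t (r + wT)(a P^b)}
#'     with terms present according to the drivers; diversity enters only as
#'     the multiplier \eqn{x_t}, never inside a competition term.}
#' }
#'
#' Rate drivers: mean-centred temperature `"T"` adds `w * T` to the base
#' rate; package origination `"O"` adds `v * O`. Limit drivers: package
#' count `"P"` turns the fixed limit into the species-area form `a P^b`;
#' temperature `"T"` multiplies by `exp(g T)` (which stays positive for
#' negative anomalies and reduces to the fixed form at `g = 0`).
#'
#' @param form one of `"scramble"`, `"contest"`, `"damped_increase"`,
#'   `"abiotic"`.
#' @param rate_drivers character subset of `c("T", "O")` (`"T"` only for
#'   abiotic).
#' @param limit_drivers character subset of `c("P", "T")` (`"P"` only for
#'   abiotic).
#' @return an object of class `model_spec`.
#' @examples
#' model_spec("contest", rate_drivers = "T", limit_drivers = c("P", "T"))
#' @export
model_spec <- function(form, rate_drivers = character(), limit_drivers = character()) {
  forms <- c("scramble", "contest", "damped_increase", "abiotic")
  form <- match.arg(form, forms)
  rate_drivers <- sort(unique(as.character(rate_drivers)))
  limit_drivers <- sort(unique(as.character(limit_drivers)))
  if (!all(rate_drivers %in% c("T", "O")))
    stop("rate_drivers must be a subset of {T, O}", call. = FALSE)
  if (!all(limit_drivers %in% c("P", "T")))
    stop("limit_drivers must be a subset of {P, T}", call. = FALSE)
  if (form == "abiotic") {
    if (!all(rate_drivers %in% "T"))
      stop("abiotic models only admit T as a rate driver", call. = FALSE)
    if (!all(limit_drivers %in% "P"))
      stop("abiotic models only admit P as a limit driver", call. = FALSE)
  }
  structure(
    list(form = form, rate_drivers = rate_drivers, limit_drivers = limit_drivers),
    class = "model_spec"
  )
}

#' Stable string identifier of a model spec
#'
#' @param spec a `model_spec`.
#' @return a string such as `"contest.rate-T.limit-PT"`; the fixed variant of
#'   a form is just the form name.
#' @export
spec_id <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  id <- spec$form
  if (length(spec$rate_drivers))
    id <- paste0(id, ".rate-", paste(spec$rate_drivers, collapse = ""))
  if (length(spec$limit_drivers))
    id <- paste0(id, ".limit-", paste(spec$limit_drivers, collapse = ""))
  id
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", spec_id(x), "\n")
  cat("  free parameters:", paste(free_params(x), collapse = ", "), "\n")
  invisible(x)
}

#' Free parameters of a model spec
#'
#' Parameter roles: `r` (scramble/abiotic base diversification rate), `k1`
#' (contest/damped discrete growth factor), `K` (fixed upper limit,
#' scramble), `k2` (density coefficient, contest/damped), `c` (competition
#' coefficient, damped), `w` (temperature coefficient on the rate, per degC),
#' `v` (origination coefficient on the rate), `a` (limit scale), `b` (limit
#' exponent, only free when P drives the limit), `g` (temperature coefficient
#' in the dynamic limit).
#'
#' @param spec a `model_spec`.
#' @return character vector of parameter names, in canonical order.
#' @export
free_params <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  ld <- spec$limit_drivers
  rd <- spec$rate_drivers
  p <- character()
  if (spec$form == "abiotic") {
    # nulls: x*r, x*(r+wT), x*(aP^b), x*(r+wT)*(aP^b)
    if (!(length(rd) == 0L && length(ld) > 0L)) p <- "r"
    if ("T" %in% rd) p <- c(p, "w")
    if ("P" %in% ld) p <- c(p, "a", "b")
    return(p)
  }
  p <- if (spec$form == "scramble") "r" else "k1"
  if ("T" %in% rd) p <- c(p, "w")
  if ("O" %in% rd) p <- c(p, "v")
  if (length(ld) == 0L) {
    p <- c(p, if (spec$form == "scramble") "K" else "k2")
  } else {
    p <- c(p, "a")
    if ("P" %in% ld) p <- c(p, "b")
    if ("T" %in% ld) p <- c(p, "g")
  }
  if (spec$form == "damped_increase") p <- c(p, "c")
  p
}

check_params <- function(spec, params) {
  need <- free_params(spec)
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameter(s) for ", spec_id(spec), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  p <- as.list(params)[need]
  pos <- intersect(c("K", "k2", "c", "a"), need)
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter ", nm, " must be > 0 (got ", p[[nm]], ")", call. = FALSE)
  }
  p
}

#' Effective per-lineage diversification rate under the drivers
#'
#' The base rate (`r` for scramble/abiotic, `k1` for contest and damped
#' increase) plus the linear driver terms `w * T` and `v * O` for whichever
#' of temperature and package origination the spec allows to act on the rate.
#'
#' @param spec a `model_spec`.
#' @param params named parameter list/vector (see [free_params()]).
#' @param T mean-centred temperature anomaly (degC); required when `"T"` is a
#'   rate driver.
#' @param O package originations in the bin; required when `"O"` is a rate
#'   driver.
#' @return effective rate (vectorised over `T`/`O`).
#' @examples
#' sp <- model_spec("scramble", rate_drivers = "T")
#' effective_rate(sp, c(r = 3, w = 0.5, K = 40), T = -2)  # 2
#' @export
effective_rate <- function(spec, params, T = NULL, O = NULL) {
  p <- check_params(spec, params)
  base_name <- if (spec$form %in% c("contest", "damped_increase")) "k1" else "r"
  rate <- if (base_name %in% names(p)) p[[base_name]] else 1
  if ("T" %in% spec$rate_drivers) {
    if (is.null(T)) stop("rate driver T required but not supplied", call. = FALSE)
    rate <- rate + p$w * T
  }
  if ("O" %in% spec$rate_drivers) {
    if (is.null(O)) stop("rate driver O required but not supplied", call. = FALSE)
    rate <- rate + p$v * O
  }
  rate
}

#' Effective upper limit / density term under the drivers
#'
#' With no limit drivers this is the fixed limit `K`. With `P` it is the
#' species-area form `a P^b`; with `T` the positive multiplier `exp(g T)`
#' scales `a` (or `a P^b`). For contest and damped-increase dynamic-limit
#' variants this quantity enters the map as the density coefficient
#' replacing `k2`, i.e. the denominator is `(1 + (a P^b) x_t)`; for scramble
#' it replaces `K` directly.
#'
#' @inheritParams effective_rate
#' @param P package count; required (and > 0) when `"P"` is a limit driver.
#' @return a strictly positive value (vectorised over `P`/`T`).
#' @examples
#' sp <- model_spec("scramble", limit_drivers = "P")
#' effective_limit(sp, c(r = 1, a = 5, b = 0.5), P = 16)  # 20
#' @export
effective_limit <- function(spec, params, P = NULL, T = NULL) {
  p <- check_params(spec, params)
  ld <- spec$limit_drivers
  if (length(ld) == 0L) {
    if (!("K" %in% names(p)))
      stop("fixed-limit value requested for a form without K; use k2 directly",
           call. = FALSE)
    return(p$K)
  }
  out <- p$a
  if ("P" %in% ld) {
    if (is.null(P)) stop("limit driver P required but not supplied", call. = FALSE)
    if (any(P <= 0)) stop("package count P must be > 0 for a dynamic limit", call. = FALSE)
    out <- out * P^p$b
  }
  if ("T" %in% ld) {
    if (is.null(T)) stop("limit driver T required but not supplied", call. = FALSE)
    out <- out * exp(p$g * T)
  }
  if (any(!is.finite(out) | out <= 0))
    stop("effective limit is not strictly positive under these parameters",
         call. = FALSE)
  out
}

#' One-step prediction of species richness
#'
#' Evaluates the selected functional form at standing richness `x` with the
#' effective rate and limit substituted for the driver combination in `spec`.
#' All biotic forms map 0 to 0. Vectorised over `x`, `T`, `P`, `O`.
#'
#' @inheritParams effective_limit
#' @param x standing species richness at the start of the step (>= 0).
#' @param O package originations in the bin.
#' @return predicted richness one bin later.
#' @examples
#' step_richness(model_spec("scramble"), c(r = 3, K = 40), x = 40)  # 40
#' step_richness(model_spec("contest"), c(k1 = 3, k2 = 0.075), x = 40)  # 30
#' @export
step_richness <- function(spec, params, x, T = NULL, P = NULL, O = NULL) {
  p <- check_params(spec, params)
  if (any(x < 0)) stop("richness x must be >= 0", call. = FALSE)
  dyn_limit <- length(spec$limit_drivers) > 0L
  if (spec$form == "abiotic") {
    fac <- if ("r" %in% names(p)) effective_rate(spec, p, T = T, O = O) else 1
    if ("P" %in% spec$limit_drivers)
      fac <- fac * effective_limit(spec, p, P = P, T = T)
    return(x * fac)
  }
  rate <- effective_rate(spec, p, T = T, O = O)
  if (spec$form == "scramble") {
    L <- if (dyn_limit) effective_limit(spec, p, P = P, T = T) else p$K
    return(x * exp(rate * (1 - x / L)))
  }
  dens <- if (dyn_limit) effective_limit(spec, p, P = P, T = T) else p$k2
  cc <- if (spec$form == "damped_increase") p$c else 1
  rate * x / (1 + dens * x)^cc
}

#' One-step predictions along a binned series
#'
#' For each transition, applies [step_richness()] to the observed richness at
#' the older edge with that bin's drivers. Predictions are never chained on
#' the model's own output (one-step-ahead regression, not free simulation).
#'
#' @param spec a `model_spec`.
#' @param params named parameters.
#' @param binned a `binned_series` from [bin_all()].
#' @return numeric vector, one prediction per transition (oldest first).
#' @export
predict_series <- function(spec, params, binned) {
  stopifnot(inherits(binned, "binned_series"))
  tr <- transitions(binned)
  if (nrow(tr) < 1L) stop("binned series has no transitions", call. = FALSE)
  step_richness(spec, params, x = tr$x, T = tr$T, P = tr$P, O = tr$O)
}

#' Enumerate the global model set
#'
#' The default global set crosses the three biotic forms with every
#' combination of rate drivers (none, T, O, T+O) and limit drivers (none, P,
#' T, P+T), and adds the four abiotic nulls (constant, T-driven rate,
#' P-driven, both): 3 x 16 + 4 = 52 specs, deduplicated, in a deterministic
#' order.
#'
#' @param forms biotic forms to include.
#' @param rate_driver_sets list of rate-driver subsets to cross.
#' @param limit_driver_sets list of limit-driver subsets to cross.
#' @param include_abiotic include the four abiotic nulls?
#' @return named list of `model_spec`s, names are [spec_id()]s.
#' @examples
#' length(build_model_set())  # 52
#' @export
build_model_set <- function(forms = c("scramble", "contest", "damped_increase"),
                            rate_driver_sets = list(character(), "T", "O", c("T", "O")),
                            limit_driver_sets = list(character(), "P", "T", c("P", "T")),
                            include_abiotic = TRUE) {
  specs <- list()
  for (f in forms)
    for (rd in rate_driver_sets)
      for (ld in limit_driver_sets)
        specs[[length(specs) + 1L]] <- model_spec(f, rd, ld)
  if (include_abiotic)
    for (rd in list(character(), "T"))
      for (ld in list(character(), "P"))
        specs[[length(specs) + 1L]] <- model_spec("abiotic", rd, ld)
  ids <- vapply(specs, spec_id, character(1))
  specs <- specs[!duplicated(ids)]
  names(specs) <- ids[!duplicated(ids)]
  specs
}

#' Implied upper limits of a contest (or damped) fit
#'
#' The contest map admits two bookkeeping conventions for its upper limit:
#' the ratio `k1/k2` (the convention under which Fig-1-style parameter sets
#' report `k2 = r/K`) and the map's actual fixed point `(k1 - 1)/k2`
#' (the richness at which one step returns its input). Both are reported;
#' neither is asserted as the single "true" limit.
#'
#' @param params named parameters containing `k1` and `k2`.
#' @return named numeric: `ratio` = k1/k2, `fixed_point` = (k1 - 1)/k2, and
#'   `k2_from_ratio` = k1/ratio (identity useful for cross-checking a limit
#'   quoted under the ratio convention).
#' @examples
#' implied_limits(c(k1 = 3, k2 = 0.075))
#' @export
implied_limits <- function(params) {
  p <- as.list(params)
  if (is.null(p$k1) || is.null(p$k2))
    stop("params must contain k1 and k2", call. = FALSE)
  ratio <- p$k1 / p$k2
  c(ratio = ratio, fixed_point = (p$k1 - 1) / p$k2, k2_from_ratio = p$k1 / ratio)
}

#' Density coefficient implied by a quoted upper limit
#'
#' Under the ratio convention `K = k1/k2`, a growth factor `k1` and quoted
#' limit `K` imply the density coefficient `k2 = k1/K` (e.g. `k1 = 3`,
#' `K = 40` gives `k2 = 0.075`).
#'
#' @param k1 discrete growth factor (> 0).
#' @param K quoted upper limit (> 0).
#' @return `k1 / K`.
#' @export
k2_for_limit <- function(k1, K) {
  stopifnot(is.numeric(k1), is.numeric(K), all(k1 > 0), all(K > 0))
  k1 / K
}
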