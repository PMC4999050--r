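#' Fitting options
#'
#' @param n_starts number of multi-start points (a seeded Latin hypercube
#'   over the parameter bounds, plus one data-informed start).
#' @param seed integer seed for the start design.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param bounds optional named list overriding default parameter bounds;
#'   each element is `c(lower, upper)`.
#' @return a `fit_options` list.
#' @export
fit_options <- function(n_starts = 25L, seed = 1L, maxiter = 200L, bounds = list()) {
  stopifnot(n_starts >= 1, maxiter >= 1)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 maxiter = as.integer(maxiter), bounds = bounds),
            class = "fit_options")
}

# Accept either a binned_series or a bare table of one-step transitions
# (columns x, x_next, T, P, O). The least-squares objective treats
# transitions as exchangeable rows, so either representation fits.
transitions_of <- function(binned) {
  if (inherits(binned, "binned_series")) return(transitions(binned))
  tr <- as.data.frame(binned)
  need <- c("x", "x_next", "T", "P", "O")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("transitions table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tr
}

# Default box constraints. Rates are dimensionless per-bin quantities; scale
# parameters (K, a) are bounded relative to the observed richness so the maps
# stay finite over the search region.
default_bounds <- function(spec, binned) {
  xmax <- max(transitions_of(binned)$x, 1)
  b <- list(
    r  = c(-10, 10),
    k1 = c(-10, 10),
    K  = c(1e-6, 10 * xmax),
    k2 = c(1e-8, 10),
    a  = c(1e-6, 10 * xmax),
    b  = c(-2, 2),
    c  = c(1e-3, 5),
    w  = c(-10, 10),
    v  = c(-10, 10),
    g  = c(-10, 10)
  )
  b[free_params(spec)]
}

# A single data-informed start: growth factor just above 1, limit near the
# observed maximum, gentle driver coefficients.
heuristic_start <- function(spec, binned) {
  xmax <- max(transitions_of(binned)$x, 1)
  defaults <- c(r = 1.5, k1 = 1.5, K = xmax, k2 = 1 / xmax,
                a = xmax, b = 0.25, c = 1, w = 0, v = 0, g = 0)
  defaults[free_params(spec)]
}

#' Fit one competition model to a binned series
#'
#' Minimises the sum of squared one-step residuals
#' \eqn{\sum_t (x_{t+1,obs} - f(x_{t,obs}))^2} by Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]), restarted from a deterministic seeded Latin
#' hypercube of starting values within the parameter bounds; the best
#' converged start is returned. Standard errors come from the Jacobian-based
#' covariance at the optimum, \eqn{\hat\sigma^2 (J'J)^{-1}} with
#' \eqn{\hat\sigma^2 = RSS/(n - p)}.
#'
#' @param spec a `model_spec`.
#' @param binned a `binned_series` with more transitions than free
#'   parameters + 1.
#' @param options a [fit_options()].
#' @return a `fit_result`: `spec_id`, `spec`, `estimates`,
#'   `standard_errors`, `rss`, `n` (transitions), `k` (free parameters + 1,
#'   counting the residual variance), `converged`, `n_starts_tried`. When no
#'   start converges, `converged = FALSE` and `rss = Inf`.
#' @export
fit_model <- function(spec, binned, options = fit_options()) {
  stopifnot(inherits(spec, "model_spec"))
  tr <- transitions_of(binned)
  pnames <- free_params(spec)
  p <- length(pnames)
  n <- nrow(tr)
  if (n <= p + 1L)
    stop("underdetermined fit: ", n, " transitions for ", p,
         " free parameters", call. = FALSE)

  bounds <- utils::modifyList(default_bounds(spec, binned), options$bounds)
  lower <- vapply(bounds, `[`, numeric(1), 1L)[pnames]
  upper <- vapply(bounds, `[`, numeric(1), 2L)[pnames]

  resid_fun <- function(theta) {
    names(theta) <- pnames
    pred <- tryCatch(
      step_richness(spec, theta, x = tr$x, T = tr$T, P = tr$P, O = tr$O),
      error = function(e) rep(NA_real_, n)
    )
    r <- tr$x_next - pred
    r[!is.finite(r)] <- 1e8
    r
  }

  starts <- withr::with_seed(options$seed, {
    u <- lhs::randomLHS(max(options$n_starts - 1L, 1L), p)
    sweep(u, 2L, upper - lower, `*`) + matrix(lower, nrow(u), p, byrow = TRUE)
  })
  start_list <- c(list(pmin(pmax(heuristic_start(spec, binned), lower), upper)),
                  if (options$n_starts > 1L)
                    lapply(seq_len(nrow(starts)), function(i) starts[i, ]))

  best <- NULL
  tried <- 0L
  for (s in start_list) {
    tried <- tried + 1L
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = options$maxiter)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$info %in% 1:3) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    return(structure(
      list(spec_id = spec_id(spec), spec = spec,
           estimates = stats::setNames(rep(NA_real_, p), pnames),
           standard_errors = NULL, rss = Inf, n = n, k = p + 1L,
           converged = FALSE, n_starts_tried = tried),
      class = "fit_result"))
  }

  est <- stats::setNames(as.numeric(best$fit$par), pnames)
  se <- tryCatch({
    cov <- chol2inv(chol(best$fit$hessian)) * best$rss / (n - p)
    stats::setNames(sqrt(pmax(diag(cov), 0)), pnames)
  }, error = function(e) stats::setNames(rep(NA_real_, p), pnames))

  structure(
    list(spec_id = spec_id(spec), spec = spec, estimates = est,
         standard_errors = se, rss = best$rss, n = n, k = p + 1L,
         converged = TRUE, n_starts_tried = tried),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$spec_id,
      sprintf("rss = %.4g, n = %d, k = %d, converged = %s\n",
              x$rss, x$n, x$k, x$converged))
  if (x$converged) {
    tab <- rbind(estimate = x$estimates, se = x$standard_errors)
    print(round(tab, 4))
  }
  invisible(x)
}

#' One-sided Wald upper confidence limit for the competition coefficient
#'
#' \eqn{\hat c + z_{level} \, SE(\hat c)}. An upper limit below 1 indicates a
#' damped increase distinct from the bounded contest (c = 1) and
#' scramble-like (c > 1) regimes.
#'
#' @param fit a converged `fit_result` of a damped-increase model.
#' @param level one-sided confidence level (default 0.95).
#' @return the upper limit for `c`.
#' @export
upper_confidence_limit_c <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "fit_result"))
  if (!("c" %in% names(fit$estimates)))
    stop("model has no competition coefficient c", call. = FALSE)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  unname(fit$estimates["c"] + stats::qnorm(level) * fit$standard_errors["c"])
}

#' Tidy table of fit results
#'
#' @param fits list of `fit_result`s (optionally with an accompanying
#'   `bin_length`).
#' @param bin_length optional bin length recycled into a column.
#' @return data.frame, one row per fit, with `spec_id`, `bin_length`, `n`,
#'   `k`, `rss`, `aicc`, `converged`, and `<param>` / `se_<param>` columns.
#' @export
fit_table <- function(fits, bin_length = NA_real_) {
  all_par <- unique(unlist(lapply(fits, function(f) names(f$estimates))))
  rows <- lapply(fits, function(f) {
    row <- data.frame(spec_id = f$spec_id, bin_length = bin_length, n = f$n,
                      k = f$k, rss = f$rss,
                      aicc = if (is.finite(f$rss) && f$rss > 0)
                        aicc(f$rss, f$n, f$k) else Inf,
                      converged = f$converged)
    for (pn in all_par) {
      row[[pn]] <- unname(f$estimates[pn])
      row[[paste0("se_", pn)]] <- if (is.null(f$standard_errors)) NA_real_
        else unname(f$standard_errors[pn])
    }
    row
  })
  do.call(rbind, rows)
}
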