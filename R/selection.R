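#' Small-sample corrected Akaike information criterion
#'
#' Gaussian least-squares form,
#' \eqn{AICc = n \ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)}, with `k` counting the
#' residual variance as a parameter.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of observations (transitions).
#' @param k number of parameters including the residual variance (>= 1,
#'   and n > k + 1 or the correction term is undefined).
#' @return the AICc score.
#' @examples
#' aicc(1, 10, 2)  # -17.3116
#' @export
aicc <- function(rss, n, k) {
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  if (n <= k + 1) stop("AICc undefined: need n > k + 1", call. = FALSE)
  if (!is.numeric(rss) || rss <= 0) stop("rss must be > 0", call. = FALSE)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AICc_i - \min AICc}. A weight quantifies the probability
#' that a model is the best of those compared. Non-finite scores (e.g.
#' non-converged fits carrying an infinite RSS sentinel) receive weight 0
#' but stay in the set, so the denominator is well defined.
#'
#' @param aiccs numeric vector of AICc scores (names preserved).
#' @return weights summing to 1.
#' @examples
#' akaike_weights(c(0, 2))  # 0.7311 0.2689
#' @export
akaike_weights <- function(aiccs) {
  ok <- is.finite(aiccs)
  if (!any(ok)) stop("no finite AICc score to weight", call. = FALSE)
  w <- numeric(length(aiccs))
  d <- aiccs[ok] - min(aiccs[ok])
  w[ok] <- exp(-d / 2)
  w <- w / sum(w)
  names(w) <- names(aiccs)
  w
}

#' Model-averaged predictions
#'
#' Multiplies each model's one-step predictions by its Akaike weight and sums
#' the weighted predictions within each bin.
#'
#' @param weights numeric weights, one per model.
#' @param predictions list (one element per model) of equal-length numeric
#'   prediction vectors, or a matrix with one row per model.
#' @return numeric vector of averaged predictions per bin.
#' @export
model_average <- function(weights, predictions) {
  if (is.list(predictions)) {
    len <- unique(vapply(predictions, length, integer(1)))
    if (length(len) != 1L)
      stop("prediction vectors are misaligned", call. = FALSE)
    predictions <- do.call(rbind, predictions)
  }
  if (length(weights) != nrow(predictions))
    stop("one weight per model required", call. = FALSE)
  as.numeric(crossprod(weights, predictions))
}

#' Sum model weights within groups
#'
#' @param weights named numeric weights (names are model ids).
#' @param grouping named list of character vectors; must partition the ids
#'   exactly (every model in exactly one group).
#' @return named numeric group weights (sum to the same total as `weights`).
#' @export
group_weights <- function(weights, grouping) {
  ids <- names(weights)
  members <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, ids))
    stop("grouping is not a partition of the model set", call. = FALSE)
  vapply(grouping, function(g) sum(weights[g]), numeric(1))
}

#' Standard groupings of a model set
#'
#' `form_grouping` groups by functional form (scramble / contest /
#' damped_increase / abiotic). `driver_grouping` groups by which
#' environmental variables leave a signature anywhere in the model (none,
#' climate only, geology only, both; temperature is climatic, package count
#' and origination are geological). `response_grouping` groups the biotic
#' models by whether the diversification rate and/or the upper limit responds
#' to the environment (abiotic models form their own group).
#'
#' @param model_set named list of `model_spec`s (names = spec ids).
#' @return named list of character vectors partitioning the ids.
#' @export
form_grouping <- function(model_set) {
  ids <- names(model_set)
  forms <- vapply(model_set, function(s) s$form, character(1))
  split(ids, factor(forms, levels = unique(forms)))
}

#' @rdname form_grouping
#' @export
driver_grouping <- function(model_set) {
  ids <- names(model_set)
  cls <- vapply(model_set, function(s) {
    climatic <- "T" %in% s$rate_drivers || "T" %in% s$limit_drivers
    geological <- "O" %in% s$rate_drivers || "P" %in% s$limit_drivers
    if (climatic && geological) "climate+geology"
    else if (climatic) "climate" else if (geological) "geology" else "none"
  }, character(1))
  split(ids, factor(cls, levels = c("none", "climate", "geology", "climate+geology")))
}

#' @rdname form_grouping
#' @export
response_grouping <- function(model_set) {
  ids <- names(model_set)
  cls <- vapply(model_set, function(s) {
    if (s$form == "abiotic") return("abiotic")
    rate <- length(s$rate_drivers) > 0L
    lim <- length(s$limit_drivers) > 0L
    if (rate && lim) "rate+limit"
    else if (rate) "rate" else if (lim) "limit" else "neither"
  }, character(1))
  split(ids, factor(cls, levels = c("neither", "rate", "limit", "rate+limit", "abiotic")))
}

# Deterministic per-(length, model) seed stream below 2^31. Keyed on the
# length value (not its position) so per-length analyses are independent of
# the order in which lengths are requested.
derive_seed <- function(master, length_value, model_index) {
  as.integer((as.numeric(master) * 48271 + round(length_value * 1000) * 10007 +
                model_index * 101) %% 2147483587) + 1L
}

#' Fit, score and weight a model set over a sweep of bin lengths
#'
#' For each bin length: discretise ([bin_all()]), fit every model
#' ([fit_model()], seeded per length and model from the master seed), score
#' by [aicc()], convert to [akaike_weights()], aggregate by the standard
#' groupings, and model-average the one-step predictions. Across lengths the
#' grouped supports are combined as unweighted arithmetic means, and the
#' damped-increase competition coefficient is summarised by the median of
#' per-length estimates and of their one-sided upper 95% confidence limits.
#'
#' Models with more free parameters than a length's transitions can support
#' are skipped at that length with a warning (and a length with no fittable
#' model is dropped entirely).
#'
#' @param durations durations table.
#' @param env environment series.
#' @param lengths bin lengths in Myr (default 0.5 to 2.0 by 0.1).
#' @param model_set named list of `model_spec`s from [build_model_set()].
#' @param seed master integer seed for the multi-start streams.
#' @param options a [fit_options()]; its seed field is overridden per
#'   (length, model).
#' @param oldest_age passed to [bin_all()].
#' @return a `sweep_result` with per-length weights, fits table, grouped
#'   supports (`by_form`, `by_driver`, `by_response`), their across-length
#'   means (`mean_support_*`), model-averaged fitted values and observations
#'   per length (`averaged`), per-length `c` summaries (`c_table`) and the
#'   medians `c_median`, `c_upper95_median`.
#' @export
sweep_bin_lengths <- function(durations, env, lengths = seq(0.5, 2.0, by = 0.1),
                              model_set = build_model_set(), seed = 1L,
                              options = fit_options(), oldest_age = NULL) {
  stopifnot(length(model_set) >= 1L, length(lengths) >= 1L)
  per_length <- list()
  fits_df <- list()
  for (li in seq_along(lengths)) {
    L <- lengths[li]
    binned <- bin_all(durations, env, L, oldest_age = oldest_age)
    tr <- transitions(binned)
    fits <- list()
    for (mi in seq_along(model_set)) {
      spec <- model_set[[mi]]
      p <- length(free_params(spec))
      if (nrow(tr) < p + 2L) {
        warning(sprintf("skipping %s at L = %g: %d transitions < %d needed",
                        names(model_set)[mi], L, nrow(tr), p + 2L))
        next
      }
      opt <- options
      opt$seed <- derive_seed(seed, L, mi)
      fits[[names(model_set)[mi]]] <- fit_model(spec, binned, opt)
    }
    if (!length(fits)) {
      warning(sprintf("no fittable model at L = %g; length dropped", L))
      next
    }
    ft <- fit_table(fits, bin_length = L)
    w <- akaike_weights(stats::setNames(ft$aicc, ft$spec_id))
    sub_set <- model_set[names(fits)]
    preds <- lapply(names(fits), function(id)
      if (fits[[id]]$converged)
        predict_series(model_set[[id]], fits[[id]]$estimates, binned)
      else rep(0, nrow(tr)))
    avg <- model_average(w, preds)
    cs <- c_summary(fits, w)
    per_length[[as.character(L)]] <- list(
      bin_length = L, binned = binned, fits = fits, weights = w,
      by_form = group_weights(w, form_grouping(sub_set)),
      by_driver = group_weights(w, driver_grouping(sub_set)),
      by_response = group_weights(w, response_grouping(sub_set)),
      averaged = data.frame(age = tr$age_younger, observed = tr$x_next,
                            fitted = avg),
      c_hat = cs[1], c_upper95 = cs[2])
    fits_df[[as.character(L)]] <- ft
  }
  if (!length(per_length)) stop("no bin length could be analysed", call. = FALSE)

  mean_rows <- function(field) {
    m <- do.call(rbind, lapply(per_length, `[[`, field))
    colMeans(m)
  }
  c_table <- data.frame(
    bin_length = vapply(per_length, `[[`, numeric(1), "bin_length"),
    c_hat = vapply(per_length, `[[`, numeric(1), "c_hat"),
    c_upper95 = vapply(per_length, `[[`, numeric(1), "c_upper95"),
    row.names = NULL)
  structure(
    list(bin_lengths = vapply(per_length, `[[`, numeric(1), "bin_length"),
         per_length = per_length,
         fits = do.call(rbind, c(fits_df, list(make.row.names = FALSE))),
         mean_support_form = mean_rows("by_form"),
         mean_support_driver = mean_rows("by_driver"),
         mean_support_response = mean_rows("by_response"),
         c_table = c_table,
         c_median = stats::median(c_table$c_hat, na.rm = TRUE),
         c_upper95_median = stats::median(c_table$c_upper95, na.rm = TRUE),
         seed = seed),
    class = "sweep_result")
}

# Per-length competition-coefficient summary: the damped-increase model with
# the largest Akaike weight supplies c-hat and its upper 95% Wald limit.
c_summary <- function(fits, weights) {
  has_c <- vapply(fits, function(f)
    f$converged && "c" %in% names(f$estimates), logical(1))
  if (!any(has_c)) return(c(NA_real_, NA_real_))
  ids <- names(fits)[has_c]
  best <- ids[which.max(weights[ids])]
  f <- fits[[best]]
  c(unname(f$estimates["c"]), upper_confidence_limit_c(f, 0.95))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>", length(x$bin_lengths), "bin lengths,",
      length(x$per_length[[1]]$weights), "models\n")
  cat("mean support by form:\n")
  print(round(x$mean_support_form, 4))
  cat("mean support by response:\n")
  print(round(x$mean_support_response, 4))
  cat(sprintf("median c = %.3f (median upper 95%% limit %.3f)\n",
              x$c_median, x$c_upper95_median))
  invisible(x)
}
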