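#' Squared correlation between observed and fitted values
#'
#' The square of the Pearson correlation: the proportion of variation in the
#' observed one-step changes captured by the (model-averaged) fitted values.
#'
#' @param observed numeric vector (length >= 3, nonzero variance).
#' @param fitted numeric vector, same length.
#' @return a proportion in [0, 1].
#' @export
squared_correlation <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 3L)
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(fitted) == 0)
    stop("zero variance in observed or fitted values", call. = FALSE)
  stats::cor(observed, fitted)^2
}

#' Residual autocorrelation with white-noise reference bounds
#'
#' Sample autocorrelation of the (model-averaged) residuals at lags
#' 1..`max_lag`, with the usual +/- 1.96/sqrt(n) white-noise bound attached.
#'
#' @param residuals numeric vector (length > max_lag + 2, nonzero variance).
#' @param max_lag largest lag.
#' @return data.frame with `lag`, `acf`, `bound`.
#' @export
residual_autocorrelation <- function(residuals, max_lag = 10L) {
  n <- length(residuals)
  if (n <= max_lag + 2L) stop("series too short for max_lag", call. = FALSE)
  if (stats::sd(residuals) == 0) stop("residuals have zero variance", call. = FALSE)
  a <- stats::acf(residuals, lag.max = max_lag, plot = FALSE, demean = TRUE)
  data.frame(lag = seq_len(max_lag),
             acf = as.numeric(a$acf)[-1L],
             bound = 1.96 / sqrt(n))
}

#' Spearman rank correlation of first differences
#'
#' Differencing removes shared drift before asking whether two series move
#' together; used to check that detection-probability-like series do not
#' track observed diversity. Significance by a seeded permutation test on
#' the differenced series.
#'
#' @param series_a,series_b numeric vectors, equal length >= 4.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return list with `rho` (Spearman correlation of the differences) and
#'   `p_value` (two-sided permutation p).
#' @export
first_difference_rank_correlation <- function(series_a, series_b,
                                              n_perm = 1000L, seed = 1L) {
  if (length(series_a) != length(series_b) || length(series_a) < 4L)
    stop("need equal-length series of length >= 4", call. = FALSE)
  da <- diff(series_a)
  db <- diff(series_b)
  if (length(unique(da)) == 1L || length(unique(db)) == 1L)
    stop("differences are constant (ties only); correlation undefined",
         call. = FALSE)
  rho <- stats::cor(da, db, method = "spearman")
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i)
      stats::cor(da, sample(db), method = "spearman"), numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_value = p)
}
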