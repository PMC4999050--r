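#' Equally spaced bin edges anchored at the present
#'
#' Edges run 0, L, 2L, ... (ascending in age, Ma before present) and extend
#' until the next edge would exceed `oldest_age`; any older partial remainder
#' is discarded, so every discretisation ends at 0 Ma.
#'
#' @param bin_length bin length L in Myr (> 0).
#' @param oldest_age oldest age to cover, Ma (>= bin_length).
#' @return numeric vector of edges in Ma, ascending from 0.
#' @examples
#' make_edges(1, 3)     # 0 1 2 3
#' length(make_edges(0.5, 65)) - 1  # 130 bins
#' @export
make_edges <- function(bin_length, oldest_age) {
  if (!is.numeric(bin_length) || length(bin_length) != 1L || bin_length <= 0)
    stop("bin_length must be a single value > 0", call. = FALSE)
  if (!is.numeric(oldest_age) || length(oldest_age) != 1L || oldest_age < bin_length)
    stop("oldest_age must be >= bin_length", call. = FALSE)
  n_bins <- floor(oldest_age / bin_length + 1e-9)
  seq(0, n_bins) * bin_length
}

#' Standing species richness at an instant
#'
#' Counts durations alive at age `t` under the convention: origination
#' inclusive, extinction exclusive, i.e. `extinction_age < t <= origin_age`.
#' A lineage flagged extant survives to the present and is counted at t = 0;
#' an unflagged lineage with extinction_age = 0 is not (it died exactly at
#' the present instant).
#'
#' @param t age in Ma (>= 0).
#' @param durations a durations table (see [read_durations()]): columns
#'   `species`, `origin_age`, `extinction_age` and optionally logical
#'   `extant`.
#' @return integer count.
#' @export
richness_at <- function(t, durations) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  d <- as_durations(durations)
  alive <- t <= d$origin_age & (d$extant | t > d$extinction_age)
  sum(alive)
}

as_durations <- function(durations) {
  d <- as.data.frame(durations)
  need <- c("species", "origin_age", "extinction_age")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("durations table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(d$extant)) d$extant <- FALSE
  bad <- which(!(d$origin_age > d$extinction_age))
  if (length(bad))
    stop("origin_age must exceed extinction_age; violated for species ",
         paste(d$species[bad], collapse = ", "), call. = FALSE)
  d
}

#' Bin an environment series
#'
#' Bins are half-open in age, `[older_edge, younger_edge)`: a sample at age
#' `s` belongs to the bin with `younger_edge < s <= older_edge`. Per bin:
#' the mean temperature (re-centred so the binned series has mean zero), the
#' mean package count rounded half-up to an integer, and the summed package
#' originations (a package origination belongs to the bin its age falls in,
#' whether or not the package persists). A bin containing no samples is an
#' error: interpolation would fabricate driver values.
#'
#' @param env an environment series (see [read_environment()]): columns
#'   `age`, `temperature`, `package_count`, `package_originations`.
#' @param edges ascending edges from [make_edges()].
#' @return list with `T_bin`, `P_bin`, `O_bin`, each of length
#'   `length(edges) - 1`, ordered oldest bin first.
#' @export
bin_environment <- function(env, edges) {
  env <- as_environment(env)
  if (length(edges) < 2L) stop("need at least two edges", call. = FALSE)
  n_bins <- length(edges) - 1L
  # bin i (oldest first) spans [edges[n_bins + 2 - i], edges[n_bins + 1 - i])
  T_bin <- P_bin <- O_bin <- numeric(n_bins)
  for (i in seq_len(n_bins)) {
    older <- edges[n_bins + 2L - i]
    younger <- edges[n_bins + 1L - i]
    in_bin <- env$age <= older & env$age > younger
    if (!any(in_bin))
      stop(sprintf("no environment samples in bin [%g, %g) Ma", older, younger),
           call. = FALSE)
    T_bin[i] <- mean(env$temperature[in_bin])
    P_bin[i] <- floor(mean(env$package_count[in_bin]) + 0.5)
    O_bin[i] <- sum(env$package_originations[in_bin])
  }
  T_bin <- T_bin - mean(T_bin)
  list(T_bin = T_bin, P_bin = P_bin, O_bin = O_bin)
}

as_environment <- function(env) {
  e <- as.data.frame(env)
  need <- c("age", "temperature", "package_count", "package_originations")
  miss <- setdiff(need, names(e))
  if (length(miss))
    stop("environment series lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(e$age))
    stop("environment ages are not strictly monotone (duplicate ages)",
         call. = FALSE)
  if (any(e$package_count < 0) || any(e$package_originations < 0))
    stop("package counts and originations must be >= 0", call. = FALSE)
  e[order(-e$age), , drop = FALSE]
}

#' Assemble a binned one-step series
#'
#' Richness is standing richness evaluated at every bin edge (instantaneous
#' counts, so x_t and x_{t+1} are the same kind of quantity); each transition
#' pairs the richness at the older edge with the richness at the younger edge
#' and the drivers of the bin between them.
#'
#' @param durations durations table.
#' @param env environment series.
#' @param bin_length bin length in Myr.
#' @param oldest_age oldest age to cover; defaults to the oldest environment
#'   sample (so every bin is guaranteed environmental coverage).
#' @return a `binned_series`: list with `bin_length`, `edges` (descending,
#'   oldest first, last = 0), `richness` (one per edge, same order), `T_bin`,
#'   `P_bin`, `O_bin` (one per bin, oldest first).
#' @export
bin_all <- function(durations, env, bin_length, oldest_age = NULL) {
  env <- as_environment(env)
  if (is.null(oldest_age)) oldest_age <- max(env$age)
  edges_asc <- make_edges(bin_length, oldest_age)
  drv <- bin_environment(env, edges_asc)
  edges <- rev(edges_asc)
  richness <- vapply(edges, richness_at, numeric(1), durations = durations)
  structure(
    list(bin_length = bin_length, edges = edges, richness = richness,
         T_bin = drv$T_bin, P_bin = drv$P_bin, O_bin = drv$O_bin),
    class = "binned_series"
  )
}

#' Construct a binned series from already-binned values
#'
#' For data that arrive pre-discretised — e.g. a richness trajectory from
#' [simulate_richness()] whose steps are the bins — rather than as raw
#' durations. `richness` holds one value per bin edge (oldest first or
#' youngest first; supplied oldest-first internally), and each driver one
#' value per bin.
#'
#' @param richness numeric vector of richness at edges, oldest edge first
#'   (length = number of bins + 1).
#' @param env environment series with exactly one sample per bin, oldest
#'   first, or a list with `T_bin`, `P_bin`, `O_bin`.
#' @param bin_length bin length in Myr.
#' @return a `binned_series`.
#' @export
as_binned_series <- function(richness, env, bin_length = 1) {
  n_bins <- length(richness) - 1L
  if (n_bins < 1L) stop("need at least two richness values", call. = FALSE)
  if (is.data.frame(env)) {
    env <- as_environment(env)
    if (nrow(env) != n_bins)
      stop("need exactly one environment sample per bin", call. = FALSE)
    drv <- list(T_bin = env$temperature - mean(env$temperature),
                P_bin = env$package_count, O_bin = env$package_originations)
  } else {
    drv <- env
    if (!all(c("T_bin", "P_bin", "O_bin") %in% names(drv)) ||
        any(lengths(drv[c("T_bin", "P_bin", "O_bin")]) != n_bins))
      stop("driver lists must have one value per bin", call. = FALSE)
  }
  structure(
    list(bin_length = bin_length,
         edges = seq(n_bins, 0) * bin_length,
         richness = richness,
         T_bin = drv$T_bin, P_bin = drv$P_bin, O_bin = drv$O_bin),
    class = "binned_series"
  )
}

#' One-step transitions of a binned series
#'
#' @param binned a `binned_series`.
#' @return data.frame, oldest transition first, with `age_older`,
#'   `age_younger`, `x` (richness at the older edge), `x_next` (richness at
#'   the younger edge) and the bin drivers `T`, `P`, `O`.
#' @export
transitions <- function(binned) {
  stopifnot(inherits(binned, "binned_series"))
  n <- length(binned$edges) - 1L
  data.frame(
    age_older = binned$edges[seq_len(n)],
    age_younger = binned$edges[seq_len(n) + 1L],
    x = binned$richness[seq_len(n)],
    x_next = binned$richness[seq_len(n) + 1L],
    T = binned$T_bin,
    P = binned$P_bin,
    O = binned$O_bin
  )
}

#' @export
print.binned_series <- function(x, ...) {
  cat("<binned_series> L =", x$bin_length, "Myr,",
      length(x$edges) - 1L, "transitions, richness",
      min(x$richness), "-", max(x$richness), "\n")
  invisible(x)
}
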