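#' Read a species-durations table
#'
#' Expects a CSV with header `species,origin_age_ma,extinction_age_ma` and an
#' optional `extant` column (logical or 0/1). Ages are Ma before present,
#' present = 0, increasing into the past. Duplicate species ids are rejected;
#' `origin_age > extinction_age` is enforced per species.
#'
#' @param path CSV file path.
#' @return data.frame with columns `species`, `origin_age`,
#'   `extinction_age`, `extant`.
#' @export
read_durations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "origin_age_ma", "extinction_age_ma")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("durations file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty durations file: ", path)
    return(data.frame(species = character(), origin_age = numeric(),
                      extinction_age = numeric(), extant = logical()))
  }
  bad <- which(!is.finite(raw$origin_age_ma) | !is.finite(raw$extinction_age_ma))
  if (length(bad))
    stop("malformed durations row(s) at line ", paste(bad + 1L, collapse = ", "),
         " of ", path, call. = FALSE)
  dup <- raw$species[duplicated(raw$species)]
  if (length(dup))
    stop("duplicate species id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  extant <- if (is.null(raw$extant)) rep(FALSE, nrow(raw)) else as.logical(raw$extant)
  d <- data.frame(species = raw$species, origin_age = raw$origin_age_ma,
                  extinction_age = raw$extinction_age_ma, extant = extant)
  as_durations(d)
}

#' Write a species-durations table
#'
#' @param durations durations table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_durations <- function(durations, path) {
  d <- as_durations(durations)
  out <- data.frame(species = d$species,
                    origin_age_ma = fmt12(d$origin_age),
                    extinction_age_ma = fmt12(d$extinction_age),
                    extant = d$extant)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an environment series
#'
#' Expects a CSV with columns `age_ma, temperature_c, package_count,
#' package_originations`. Rows are sorted oldest-first; duplicate ages are an
#' error, as are negative counts. The temperature column is mean-centred on
#' load and the applied offset is reported (message and `offset` attribute).
#'
#' @param path CSV file path.
#' @return data.frame with columns `age`, `temperature` (mean-centred degC),
#'   `package_count`, `package_originations`, plus attribute `offset` (the
#'   subtracted mean, degC).
#' @export
read_environment <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_ma", "temperature_c", "package_count", "package_originations")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("environment file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  offset <- mean(raw$temperature_c)
  env <- data.frame(age = raw$age_ma,
                    temperature = raw$temperature_c - offset,
                    package_count = raw$package_count,
                    package_originations = raw$package_originations)
  env <- as_environment(env)  # sorts oldest-first, validates
  message(sprintf("temperature mean-centred on load; offset = %g degC", offset))
  attr(env, "offset") <- offset
  env
}

#' Write an environment series
#'
#' Writes `age_ma, temperature_c, package_count, package_originations`; note
#' the temperature written is whatever the series holds (mean-centred if it
#' came from [read_environment()] or [simulate_environment()]).
#'
#' @param env environment series.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_environment <- function(env, path) {
  e <- as_environment(env)
  out <- data.frame(age_ma = fmt12(e$age),
                    temperature_c = fmt12(e$temperature),
                    package_count = e$package_count,
                    package_originations = e$package_originations)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 12 significant digits: enough for lossless round trips at the precision the
# pipeline promises.
fmt12 <- function(x) sprintf("%.12g", x)
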