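test_that("AICc follows the Gaussian least-squares form", {
  expect_equal(aicc(1, 10, 2), 10 * log(0.1) + 4 + 12 / 7, tolerance = 1e-12)
  expect_equal(round(aicc(1, 10, 2), 4), -17.3116)
  # doubling the RSS at fixed n, k adds n * ln 2
  expect_equal(aicc(2, 50, 3) - aicc(1, 50, 3), 50 * log(2), tolerance = 1e-12)
  expect_error(aicc(1, 10, 0), "k")
  expect_error(aicc(1, 4, 3), "n > k \\+ 1")
  expect_error(aicc(0, 10, 2), "rss")
})

test_that("Akaike weights normalise, shift-invariantly, with non-finite scores zeroed", {
  expect_equal(akaike_weights(c(0, 0)), c(0.5, 0.5))
  expect_equal(round(akaike_weights(c(0, 2)), 4), c(0.7311, 0.2689))
  w1 <- akaike_weights(c(-120.3, -118.1, -121.7))
  w2 <- akaike_weights(c(-120.3, -118.1, -121.7) + 57.3)
  expect_equal(w1, w2, tolerance = 1e-12)
  expect_equal(sum(w1), 1, tolerance = 1e-12)
  w3 <- akaike_weights(c(0, Inf, 2, NA))
  expect_equal(w3[c(2, 4)], c(0, 0))
  expect_equal(sum(w3), 1, tolerance = 1e-12)
  expect_error(akaike_weights(c(Inf, NA)), "no finite")
})

test_that("model averaging is the weighted elementwise sum", {
  expect_equal(model_average(c(0.25, 0.75), list(rep(10, 4), rep(20, 4))),
               rep(17.5, 4))
  expect_equal(model_average(c(1, 0), list(1:5, 6:10)), 1:5, ignore_attr = TRUE)
  same <- list(c(3, 1, 4), c(3, 1, 4), c(3, 1, 4))
  expect_equal(model_average(c(0.2, 0.3, 0.5), same), c(3, 1, 4))
  expect_error(model_average(c(0.5, 0.5), list(1:3, 1:4)), "misaligned")
})

test_that("group weights require a partition and respect associativity", {
  w <- c(a1 = 0.1, a2 = 0.2, b1 = 0.3, b2 = 0.4)
  expect_equal(group_weights(w, list(all = names(w))), c(all = 1))
  gw <- group_weights(w, list(a = c("a1", "a2"), b = c("b1", "b2")))
  expect_equal(gw, c(a = 0.3, b = 0.7))
  expect_error(group_weights(w, list(a = c("a1", "a2"), b = "b1")), "partition")
  expect_error(group_weights(w, list(a = names(w), b = "b1")), "partition")
  # equal weights over one model per form give 0.25 each
  mset <- fixed_plus_nulls()[c("scramble", "contest", "damped_increase", "abiotic")]
  weq <- stats::setNames(rep(0.25, 4), names(mset))
  expect_equal(unname(group_weights(weq, form_grouping(mset))), rep(0.25, 4))
})

test_that("standard groupings partition the full 52-model set", {
  mset <- build_model_set()
  fg <- form_grouping(mset)
  expect_equal(lengths(fg)[c("scramble", "contest", "damped_increase", "abiotic")],
               c(scramble = 16L, contest = 16L, damped_increase = 16L, abiotic = 4L))
  dg <- driver_grouping(mset)
  expect_equal(sum(lengths(dg)), 52)
  # the driver-free group: three fixed biotic forms + the constant null
  expect_setequal(dg$none, c("scramble", "contest", "damped_increase", "abiotic"))
  rg <- response_grouping(mset)
  expect_equal(sum(lengths(rg)), 52)
  expect_equal(lengths(rg)[["abiotic"]], 4L)
  # form-first and driver-first summation agree for any weights
  w <- withr::with_seed(5, {
    raw <- runif(52)
    stats::setNames(raw / sum(raw), names(mset))
  })
  expect_equal(sum(group_weights(w, dg)), sum(group_weights(w, fg)),
               tolerance = 1e-12)
  expect_equal(sum(group_weights(w, dg)), 1, tolerance = 1e-9)
})

test_that("a single-model sweep has support one everywhere", {
  d <- simulate_durations(seed = 31, 0.35, 0.2, 40, 65)
  env <- simulate_environment(simulation_config(n_steps = 130, step_length = 0.5,
                                                seed = 31))
  sw <- suppressWarnings(sweep_bin_lengths(
    d, env, lengths = c(1.0), model_set = build_model_set(
      forms = "contest", rate_driver_sets = list(character()),
      limit_driver_sets = list(character()), include_abiotic = FALSE),
    seed = 1, options = fit_options(n_starts = 5), oldest_age = 65))
  expect_equal(unname(sw$per_length[["1"]]$weights), 1)
  expect_equal(unname(sw$mean_support_form["contest"]), 1)
  expect_equal(nrow(sw$per_length[["1"]]$averaged), 65)
})

test_that("sweeps are reproducible and invariant to length ordering", {
  d <- simulate_durations(seed = 32, 0.35, 0.2, 40, 65)
  env <- simulate_environment(simulation_config(n_steps = 650, step_length = 0.1,
                                                seed = 32))
  mset <- fixed_plus_nulls()
  sw1 <- sweep_bin_lengths(d, env, lengths = c(0.5, 1, 2), model_set = mset,
                           seed = 7, options = fit_options(n_starts = 5),
                           oldest_age = 65)
  sw2 <- sweep_bin_lengths(d, env, lengths = c(0.5, 1, 2), model_set = mset,
                           seed = 7, options = fit_options(n_starts = 5),
                           oldest_age = 65)
  expect_identical(sw1$fits, sw2$fits)
  expect_identical(sw1$mean_support_form, sw2$mean_support_form)
  sw3 <- sweep_bin_lengths(d, env, lengths = c(2, 0.5, 1), model_set = mset,
                           seed = 7, options = fit_options(n_starts = 5),
                           oldest_age = 65)
  # per-length seeds are keyed on the length value, so mean support across
  # lengths does not depend on the order lengths are requested in
  expect_equal(sw3$mean_support_form, sw1$mean_support_form, tolerance = 1e-12)
  expect_equal(sw3$mean_support_response, sw1$mean_support_response,
               tolerance = 1e-12)
  for (L in names(sw1$per_length))
    expect_identical(sw1$per_length[[L]]$weights, sw3$per_length[[L]]$weights)
  # weights sum to one at every level and length
  for (L in names(sw1$per_length)) {
    pl <- sw1$per_length[[L]]
    expect_equal(sum(pl$weights), 1, tolerance = 1e-9)
    expect_equal(sum(pl$by_form), 1, tolerance = 1e-9)
    expect_equal(sum(pl$by_driver), 1, tolerance = 1e-9)
    expect_equal(sum(pl$by_response), 1, tolerance = 1e-9)
  }
})
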