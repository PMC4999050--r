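test_that("one-step maps evaluate the schematic parameter sets correctly", {
  # scramble equilibrium is a fixed point
  expect_equal(step_richness(model_spec("scramble"), fig_params$scramble, 40), 40)
  # contest: 3*40 / (1 + 0.075*40) = 30
  expect_equal(step_richness(model_spec("contest"), fig_params$contest, 40), 30)
  # damped: 120 / 4^0.5 = 60
  expect_equal(
    step_richness(model_spec("damped_increase"), fig_params$damped_increase, 40),
    60)
  # all biotic forms map 0 to 0
  for (form in names(fig_params))
    expect_equal(step_richness(model_spec(form), fig_params[[form]], 0), 0)
})

test_that("effective rate is the base rate plus linear driver terms", {
  sp_t <- model_spec("scramble", rate_drivers = "T")
  expect_equal(effective_rate(sp_t, c(r = 3, w = 0.5, K = 40), T = -2), 2)
  sp_to <- model_spec("scramble", rate_drivers = c("T", "O"))
  expect_equal(
    effective_rate(sp_to, c(r = 1, w = 1, v = 1, K = 40), T = 0.5, O = 2), 3.5)
  # zero coefficients reduce to the fixed model
  expect_equal(effective_rate(sp_to, c(r = 3, w = 0, v = 0, K = 40), T = 5, O = 9), 3)
  expect_error(effective_rate(sp_t, c(r = 3, w = 0.5, K = 40)), "driver T")
})

test_that("effective limit follows the species-area and temperature forms", {
  sp_p <- model_spec("scramble", limit_drivers = "P")
  expect_equal(effective_limit(sp_p, c(r = 1, a = 5, b = 0.5), P = 16), 20)
  expect_equal(effective_limit(sp_p, c(r = 1, a = 7, b = 0), P = 16), 7)
  # g = 0 makes the {P,T} variant identical to the {P} variant
  sp_pt <- model_spec("scramble", limit_drivers = c("P", "T"))
  expect_equal(
    effective_limit(sp_pt, c(r = 1, a = 5, b = 0.5, g = 0), P = 16, T = -3),
    effective_limit(sp_p, c(r = 1, a = 5, b = 0.5), P = 16))
  expect_error(effective_limit(sp_p, c(r = 1, a = 5, b = 0.5), P = 0), "P must be > 0")
})

test_that("one-step predictions along a binned series are not chained", {
  b <- sim_binned("contest", noise_sd = 0)
  pred <- predict_series(model_spec("contest"), fig_params$contest, b)
  tr <- transitions(b)
  # noise-free trajectory: predictions equal the next observed value
  expect_equal(pred, tr$x_next, tolerance = 1e-12)
  # constant observed series at a fixed point predicts itself
  b2 <- as_binned_series(rep(40, 11), flat_env(10))
  expect_equal(predict_series(model_spec("scramble"), fig_params$scramble, b2),
               rep(40, 10))
  # damped with c = 1 is algebraically contest
  b3 <- sim_binned("contest", noise_sd = 1)
  expect_equal(
    predict_series(model_spec("damped_increase"), c(k1 = 3, k2 = 0.075, c = 1), b3),
    predict_series(model_spec("contest"), fig_params$contest, b3))
})

test_that("Hassell with c = 1 equals Beverton-Holt at machine precision", {
  xs <- c(0, 0.1, 1, 7, 26.7, 40, 150, 1e4)
  expect_identical(
    step_richness(model_spec("damped_increase"), c(k1 = 3, k2 = 0.075, c = 1), xs),
    step_richness(model_spec("contest"), c(k1 = 3, k2 = 0.075), xs))
})

test_that("Beverton-Holt recursion matches its closed-form solution", {
  k1 <- 3; k2 <- 0.075; x0 <- 1
  E <- (k1 - 1) / k2
  traj <- iterate_map(model_spec("contest"), c(k1 = k1, k2 = k2), x0, 50)
  closed <- E * x0 / (x0 + (E - x0) * k1^(-(0:50)))
  expect_equal(traj, closed, tolerance = 1e-9)
})

test_that("contest trajectories are non-decreasing from below and never overshoot", {
  for (k1 in c(1.5, 3, 6)) {
    k2 <- 0.075
    eq <- (k1 - 1) / k2
    traj <- iterate_map(model_spec("contest"), c(k1 = k1, k2 = k2), 1, 100)
    expect_true(all(diff(traj) >= 0))
    expect_true(all(traj <= eq + 1e-9))
  }
})

test_that("scramble at r = 3 overshoots K and crashes below it", {
  traj <- iterate_map(model_spec("scramble"), fig_params$scramble, 1, 20)
  over <- which(traj > 40)
  expect_true(length(over) > 0)
  expect_true(any(traj[seq(min(over) + 1, 21)] < 40))
})

test_that("damped increase keeps rising past the contest-equivalent limit", {
  # with c = 0.5 the trajectory passes k1/k2 = 40 and climbs monotonically
  # toward the Hassell fixed point (k1^(1/c) - 1)/k2 = 106.67
  traj <- iterate_map(model_spec("damped_increase"), fig_params$damped_increase,
                      1, 200)
  expect_true(all(diff(traj) >= 0))
  expect_gt(max(traj), 40)
  expect_equal(traj[201], (3^2 - 1) / 0.075, tolerance = 1e-6)
  # with a small competition coefficient the rise dwarfs any multiple of the
  # contest limit: c = 0.2 exceeds 10 * (k1/k2)
  traj2 <- iterate_map(model_spec("damped_increase"), c(k1 = 3, k2 = 0.075, c = 0.2),
                       1, 500)
  expect_gt(max(traj2), 10 * (3 / 0.075))
})

test_that("the global model set enumerates 52 distinct specs", {
  full <- build_model_set()
  expect_length(full, 52)
  expect_false(anyDuplicated(names(full)) > 0)
  # 3 biotic fixed-parameter specs; 4 abiotic nulls
  expect_length(build_model_set(rate_driver_sets = list(character()),
                                limit_driver_sets = list(character()),
                                include_abiotic = FALSE), 3)
  expect_length(build_model_set(forms = character(0), include_abiotic = TRUE), 4)
  # deterministic ordering
  expect_identical(names(build_model_set()), names(full))
})

test_that("spec ids are stable and parameters match the driver structure", {
  sp <- model_spec("contest", rate_drivers = "T", limit_drivers = c("P", "T"))
  expect_identical(spec_id(sp), "contest.rate-T.limit-PT")
  expect_identical(free_params(sp), c("k1", "w", "a", "b", "g"))
  expect_identical(free_params(model_spec("damped_increase")), c("k1", "k2", "c"))
  expect_identical(free_params(model_spec("abiotic", limit_drivers = "P")),
                   c("a", "b"))
  expect_error(model_spec("abiotic", rate_drivers = "O"), "abiotic")
})

test_that("both upper-limit bookkeeping conventions are reported", {
  lims <- implied_limits(c(k1 = 3, k2 = 0.075))
  expect_equal(unname(lims["ratio"]), 40)
  expect_equal(unname(lims["fixed_point"]), 2 / 0.075)
  expect_identical(k2_for_limit(3, 40), 0.075)
})

test_that("invalid parameter regions are rejected", {
  expect_error(step_richness(model_spec("scramble"), c(r = 3, K = -1), 10), "K")
  expect_error(step_richness(model_spec("contest"), c(k1 = 3, k2 = 0), 10), "k2")
  expect_error(step_richness(model_spec("scramble"), c(r = 3, K = 40), -2), "x")
  expect_error(step_richness(model_spec("contest"), c(k1 = 3), 10), "missing")
})
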