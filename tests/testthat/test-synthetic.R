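test_that("scenario invariants are enforced with the offending field named", {
  expect_error(gait_scenario(gct_left = -1), "gct_left")
  expect_error(gait_scenario(noise_sd = -0.1), "noise_sd")
  expect_error(gait_scenario(swing_fraction_left = 1.2), "swing_fraction_left")
  expect_error(
    gait_scenario(
      swing_fraction_left = 0.5, ids_fraction = 0.3, tds_fraction = 0.3
    ),
    "swing_fraction_left.*ids_fraction.*tds_fraction"
  )
  expect_error(gait_scenario(turn_start = 5), "turn_duration")
})

test_that("generation is deterministic: same seed gives bit-identical trials", {
  a <- generate_trial(gait_scenario(seed = 42, n_cycles_per_side = 4))
  b <- generate_trial(gait_scenario(seed = 42, n_cycles_per_side = 4))
  expect_identical(a$trial$markers, b$trial$markers)
  c <- generate_trial(gait_scenario(seed = 43, n_cycles_per_side = 4))
  expect_false(identical(a$trial$markers, c$trial$markers))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_trial(gait_scenario(seed = 1, n_cycles_per_side = 3)))
  expect_identical(.Random.seed, before)
})

test_that("ground truth realizes the configured gait exactly at zero noise", {
  sim <- small_sim(n = 6, seed = 2, gct_left = 1.3, gct_right = 1.3)
  gt <- ground_truth_parameters(sim$truth)
  expect_true(all(abs(gt$gct - 1.3) < 1e-12))
  # swing + stance = cycle time exactly, by construction
  expect_identical(gt$sw + gt$st, gt$gct)
  # heel-z excursion equals the step height at zero noise (up to the
  # discretization of the 100 Hz sample grid around the extrema)
  z <- sim$trial$markers$left_heel[, "z"]
  expect_lt(abs((max(z) - min(z)) - 21.2), 0.05)
  # left and right records identical for a symmetric scenario
  l <- gt[gt$side == "left", -1]
  r <- gt[gt$side == "right", -1]
  expect_equal(l, r, ignore_attr = TRUE)
})

test_that("ground-truth records follow the event-time definitions", {
  sim <- small_sim(n = 4, seed = 3)
  tr <- sim$truth$left
  gt <- ground_truth_parameters(sim$truth)
  l <- gt[gt$side == "left", ]
  expect_equal(l$gct, diff(tr$heel_valley_times), tolerance = 1e-12)
  expect_equal(
    l$ids,
    tr$toe_valley_times - tr$heel_valley_times[seq_along(tr$toe_valley_times)],
    tolerance = 1e-12
  )
  expect_true(all(is.na(l$sl[1]) & !is.na(l$sl[-1])))
  expect_equal(l$vel[-1], l$sl[-1] / l$gct[-1], tolerance = 1e-12)
})

test_that("an asymmetric cycle-time scenario yields the forced asymmetry index", {
  sim <- generate_trial(
    quiet_scenario(gct_left = 1.0, gct_right = 0.9, n_cycles_per_side = 5)
  )
  gt <- ground_truth_parameters(sim$truth)
  ia <- asymmetry_index(
    mean(gt$gct[gt$side == "left"]), mean(gt$gct[gt$side == "right"])
  )
  expect_equal(ia, 10, tolerance = 1e-9)
})

test_that("turn scenarios rotate the heading but keep vertical cycling", {
  sim <- generate_trial(gait_scenario(
    noise_sd = 0, turn_start = 5, turn_duration = 2, seed = 8
  ))
  expect_equal(sim$trial$turn_window, c(5, 7))
  heel <- sim$trial$markers$left_heel
  t <- sim$trial$time
  # before the turn: progression along x, y nearly constant
  pre <- t < 4.5
  post <- t > 8
  expect_gt(diff(range(heel[pre, "x"])), 10 * diff(range(heel[pre, "y"])))
  # after the 90-degree turn: progression along y
  expect_gt(diff(range(heel[post, "y"])), 10 * diff(range(heel[post, "x"])))
  # vertical excursion is unaffected inside the turn
  turn <- t >= 5 & t <= 7
  expect_gt(diff(range(heel[turn, "z"])), 15)
})
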