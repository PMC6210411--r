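smoothed_side <- function(sim, side = "left") {
  z <- sim$trial$markers[[paste0(side, "_heel")]][, "z"]
  smooth_signal(z, sim$trial$sampling_rate)
}

test_that("a noiseless 5-cycle trial yields exactly 6 valleys and 5 peaks", {
  sim <- small_sim(n = 5, seed = 21)
  ev <- enforce_alternation(
    detect_extrema(smoothed_side(sim), fs = 100)
  )
  expect_equal(sum(ev$events$kind == "valley"), 6)
  expect_equal(sum(ev$events$kind == "peak"), 5)
})

test_that("0.2 cm noise does not change event counts at 1 cm prominence", {
  sim <- generate_trial(gait_scenario(
    n_cycles_per_side = 5, noise_sd = 0.2, seed = 22
  ))
  ev <- enforce_alternation(
    detect_extrema(smoothed_side(sim), fs = 100, min_prominence = 1)
  )
  expect_equal(sum(ev$events$kind == "valley"), 6)
  expect_equal(sum(ev$events$kind == "peak"), 5)
  # detected valleys align with ground truth
  vt <- ev$events$time[ev$events$kind == "valley"]
  expect_true(all(abs(vt - sim$truth$left$heel_valley_times) < 0.05))
})

test_that("flat and near-flat signals raise insufficient-cycles errors", {
  expect_error(
    detect_extrema(rep(1, 500), 100),
    "insufficient cycles", class = "gaitmark_insufficient_cycles"
  )
  expect_error(
    detect_extrema(rnorm(500, sd = 0.01), 100, min_prominence = 2),
    "insufficient cycles", class = "gaitmark_insufficient_cycles"
  )
})

test_that("the one-peak-between-valleys rule keeps only the highest peak", {
  cand <- data.frame(
    kind = c("valley", "peak", "peak", "valley"),
    time = c(1.0, 1.3, 1.5, 2.3),
    height = c(0, 18, 12, 0)
  )
  ev <- enforce_alternation(cand)
  expect_equal(nrow(ev$events), 3)
  expect_equal(ev$events$time[ev$events$kind == "peak"], 1.3)
})

test_that("equal-height duplicate events keep the earlier one", {
  cand <- data.frame(
    kind = c("valley", "peak", "peak", "valley"),
    time = c(1.0, 1.3, 1.5, 2.3),
    height = c(0, 18, 18, 0)
  )
  ev <- enforce_alternation(cand)
  expect_equal(ev$events$time[ev$events$kind == "peak"], 1.3)
})

test_that("already-alternating series pass through unchanged", {
  cand <- data.frame(
    kind = c("valley", "peak", "valley", "peak", "valley"),
    time = c(1, 1.6, 2.3, 2.9, 3.6),
    height = c(0, 18, 0.2, 17, 0.1)
  )
  ev <- enforce_alternation(cand)
  expect_equal(ev$events$time, cand$time)
  expect_equal(ev$events$height, cand$height)
})

test_that("alternation enforcement is invariant-preserving and idempotent on random candidates", {
  for (seed in 1:40) {
    cand <- random_candidates(n = sample(6:40, 1), seed = seed)
    ev <- tryCatch(
      enforce_alternation(cand),
      gaitmark_insufficient_cycles = function(e) NULL
    )
    if (is.null(ev)) next
    expect_alternating(ev)
    again <- enforce_alternation(ev$events)
    expect_equal(again$events, ev$events)
  }
})

test_that("turn-window exclusion drops whole overlapping cycles only", {
  sim <- small_sim(n = 5, seed = 23)
  ev <- enforce_alternation(detect_extrema(smoothed_side(sim), fs = 100))
  # window outside the trial: identity
  same <- exclude_turn_window(ev, c(100, 101))
  expect_true(all(same$cycles$kept))
  # window inside cycle 3: exactly that cycle dropped
  c3 <- ev$cycles[3, ]
  mid <- (c3$t_start + c3$t_end) / 2
  ex <- exclude_turn_window(ev, c(mid - 0.05, mid + 0.05))
  expect_equal(sum(!ex$cycles$kept), 1)
  expect_false(ex$cycles$kept[3])
  # dropped cycles are whole: remaining cycles untouched
  expect_identical(ex$cycles[-3, c("t_start", "t_end")],
    ev$cycles[-3, c("t_start", "t_end")])
  # window spanning everything: nothing kept
  all_ex <- exclude_turn_window(ev, range(ev$events$time) + c(-1, 1))
  expect_true(all(!all_ex$cycles$kept))
  expect_error(
    compute_cycles(all_ex, fs = 100),
    "insufficient cycles", class = "gaitmark_insufficient_cycles"
  )
})

test_that("toe valleys land within one sample of the generated toe-flat times", {
  sim <- small_sim(n = 5, seed = 24)
  fs <- 100
  ev <- refine_events(
    enforce_alternation(detect_extrema(smoothed_side(sim), fs)),
    sim$trial$markers$left_heel[, "z"], fs
  )
  toe_s <- smooth_signal(sim$trial$markers$left_toe[, "z"], fs)
  tv <- match_toe_valleys(
    ev, toe_s, fs,
    toe_z_raw = sim$trial$markers$left_toe[, "z"], min_prominence = 1
  )
  expect_false(any(tv$flagged))
  expect_true(all(abs(tv$t_toe - sim$truth$left$toe_valley_times) < 1 / fs))
})

test_that("a constant toe signal flags every cycle as missing", {
  sim <- small_sim(n = 4, seed = 25)
  ev <- enforce_alternation(detect_extrema(smoothed_side(sim), 100))
  tv <- match_toe_valleys(ev, rep(2, length(sim$trial$time)), 100)
  expect_true(all(tv$flagged))
  expect_true(all(is.na(tv$t_toe)))
})

test_that("raw-signal refinement removes the smoothing lag of event times", {
  sim <- small_sim(n = 6, seed = 26)
  fs <- 100
  raw <- sim$trial$markers$left_heel[, "z"]
  ev0 <- enforce_alternation(detect_extrema(smooth_signal(raw, fs), fs))
  ev1 <- refine_events(ev0, raw, fs)
  truth_pk <- sim$truth$left$heel_peak_times
  pk0 <- ev0$events$time[ev0$events$kind == "peak"]
  pk1 <- ev1$events$time[ev1$events$kind == "peak"]
  err0 <- max(abs(pk0 - truth_pk))
  err1 <- max(abs(pk1 - truth_pk))
  expect_lt(err1, 0.1 / fs) # refined: well under a tenth of a sample
  expect_lte(err1, err0)
  # refined heights are amplitude-true
  hp <- ev1$events$height[ev1$events$kind == "peak"]
  expect_true(all(abs(hp - 21.2) < 0.05))
})
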