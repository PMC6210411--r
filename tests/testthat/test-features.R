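manual_events <- function() {
  enforce_alternation(data.frame(
    kind = c("valley", "peak", "valley"),
    time = c(1.00, 1.94, 2.29),
    height = c(0, 18, 0)
  ))
}

test_that("cycle arithmetic follows the event-time definitions", {
  ev <- manual_events()
  cyc <- compute_cycles(ev, fs = 100)
  expect_equal(cyc$gct, 1.29, tolerance = 1e-12)
  expect_equal(cyc$sw, 0.35, tolerance = 1e-12)
  expect_equal(cyc$st, 0.94, tolerance = 1e-12)
  expect_equal(cyc$sh, 18, tolerance = 1e-12)
  expect_true(cyc$valid)
})

test_that("double-support split comes from the toe-flat valley", {
  ev <- manual_events()
  toe <- data.frame(k = 1, t_toe = 1.24, flagged = FALSE)
  cyc <- compute_cycles(ev, toe, fs = 100)
  expect_equal(cyc$ids, 0.24, tolerance = 1e-12)
  expect_equal(cyc$tds, 0.70, tolerance = 1e-12)
  # a toe valley exactly at the heel valley is the running limit: IDS = 0
  toe0 <- data.frame(k = 1, t_toe = 1.00, flagged = FALSE)
  expect_equal(compute_cycles(ev, toe0, fs = 100)$ids, 0, tolerance = 1e-12)
})

test_that("pipeline records equal ground-truth records on a noiseless trial", {
  sim <- small_sim(n = 6, seed = 31)
  gt <- ground_truth_parameters(sim$truth)
  det <- extract_cycles(sim$trial)
  expect_equal(nrow(det), nrow(gt))
  for (p in c("gct", "sw", "st", "ids", "tds")) {
    expect_true(all(abs(det[[p]] - gt[[p]]) < 1 / 100), label = p)
  }
  expect_true(all(abs(det$sh - gt$sh) < 0.1))
  expect_true(all(abs(det$sl - gt$sl) < 0.1, na.rm = TRUE))
})

test_that("the definitional identities hold for every extracted record", {
  sim <- generate_trial(gait_scenario(seed = 32, noise_sd = 0.2))
  det <- extract_cycles(sim$trial)
  expect_equal(det$gct, det$sw + det$st, tolerance = 1e-12)
  expect_equal(det$sl, det$vel * det$gct, tolerance = 1e-12)
  ok <- !is.na(det$ids) & !is.na(det$tds)
  expect_true(all(det$ids[ok] + det$tds[ok] <= det$st[ok] + 1e-9))
})

test_that("time scaling propagates correctly through cycle computation", {
  base <- data.frame(
    kind = c("valley", "peak", "valley", "peak", "valley"),
    time = c(1, 1.9, 2.3, 3.2, 3.6),
    height = c(0, 18, 0, 18, 0)
  )
  a <- 1.7
  scaled <- transform(base, time = time * a)
  c1 <- compute_cycles(enforce_alternation(base), fs = 100)
  c2 <- compute_cycles(enforce_alternation(scaled), fs = 100)
  for (p in c("gct", "sw", "st")) {
    expect_equal(c2[[p]], a * c1[[p]], tolerance = 1e-12, label = p)
  }
  expect_equal(c2$sh, c1$sh, tolerance = 1e-12)
})

test_that("mis-ordered events flag the cycle instead of clamping", {
  ev <- manual_events()
  toe_bad <- data.frame(k = 1, t_toe = 2.10, flagged = FALSE) # after the peak
  cyc <- compute_cycles(ev, toe_bad, fs = 100)
  expect_false(cyc$valid)
  expect_lt(cyc$tds, 0) # reported, not clamped
})

test_that("condition summaries use mean-based ratios and per-cycle velocity", {
  sim <- small_sim(n = 8, seed = 33, gct_left = 1.4, gct_right = 1.4)
  det <- extract_cycles(sim$trial)
  s <- summarize_condition(det, "sim")
  m <- function(p) s$parameters$mean[s$parameters$parameter == p]
  r <- function(x) s$ratios$value_pct[s$ratios$ratio == x]
  expect_equal(m("gct"), 1.4, tolerance = 0.01)
  expect_equal(r("st_gct"), 100 * m("st") / m("gct"), tolerance = 1e-9)
  # internal consistency: IDS/ST = (IDS/GCT)/(ST/GCT)
  expect_equal(
    r("ids_st"), 100 * r("ids_gct") / r("st_gct"),
    tolerance = 0.01
  )
  expect_equal(m("vel"), mean(det$vel, na.rm = TRUE), tolerance = 1e-12)
  # recovery of generating values
  expect_equal(m("sw"), 0.27 * 1.4, tolerance = 0.01)
  expect_equal(m("sl"), 93, tolerance = 0.5)
})

test_that("identical records summarize with zero dispersion", {
  rec <- data.frame(
    gct = rep(1.3, 5), sw = 0.35, st = 0.95, ids = 0.24, tds = 0.2,
    sl = 90, sh = 20, vel = 90 / 1.3, valid = TRUE
  )
  s <- summarize_condition(rec, "x")
  expect_true(all(s$parameters$sd == 0))
  expect_error(
    summarize_condition(rec[0, ], "x"),
    "insufficient cycles", class = "gaitmark_insufficient_cycles"
  )
})

test_that("published-table routines verify the printed identities", {
  ref <- gait_reference_tables()
  red <- double_support_reduction(ref$ratios, "c", "mm")
  expect_equal(red$ids, 3.09, tolerance = 1e-9)
  expect_equal(red$tds, 1.79, tolerance = 1e-9)
  der <- derived_support_ratios(ref$ratios)
  mm <- der[der$condition == "mm" & der$ratio == "ids_st", ]
  expect_equal(mm$derived_pct, 100 * 15.66 / 73.10, tolerance = 1e-9)
})
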