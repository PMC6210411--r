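test_that("normality screening behaves across sample shapes", {
  expect_error(test_normality(c(1, 2)), class = "gaitmark_sample_size_error")
  # degenerate constant sample is flagged, not fatal
  res <- test_normality(rep(1.3, 10))
  expect_true(res$flagged)
  expect_true(is.na(res$p_value))
  # large Gaussian samples are flagged at about the nominal 5% rate
  set.seed(51)
  flags <- replicate(400, test_normality(rnorm(100))$flagged)
  expect_lt(abs(mean(flags) - 0.05), 0.03)
  # heavy skew is caught with high probability
  set.seed(52)
  skew_flags <- replicate(50, test_normality(rexp(200))$flagged)
  expect_gt(mean(skew_flags), 0.99)
})

test_that("comparing a group with itself gives t = 0, p = 1", {
  set.seed(53)
  x <- rnorm(30, 1.3, 0.2)
  res <- compare_conditions(x, x)
  expect_equal(res$t_statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_false(res$significant)
})

test_that("a one-SD mean shift at n = 30 is detected with high power", {
  # closed-form Welch/pooled power at delta = 1 SD, n = 30/30, alpha 0.05
  # is about 0.97; simulated power must clear 0.9
  set.seed(54)
  hits <- replicate(300, {
    compare_conditions(rnorm(30), rnorm(30, 1))$significant
  })
  expect_gt(mean(hits), 0.9)
})

test_that("sample-size and input contracts are enforced", {
  expect_error(
    compare_conditions(1, rnorm(10)),
    class = "gaitmark_sample_size_error"
  )
  df <- data.frame(gct = rnorm(10, 1.3, 0.1))
  res <- compare_conditions(df, df, parameter = "gct")
  expect_identical(res$parameter, "gct")
  expect_error(compare_conditions(df, df, parameter = "nope"), "column")
})

test_that("the per-trial report orders trials by cue-speed notation", {
  set.seed(55)
  mk <- function(trial, side, gct_sd) {
    data.frame(
      trial = trial, side = side,
      gct = rnorm(8, 1.4, gct_sd)
    )
  }
  # inflated variability in the first motorized trials, then settled
  cyc <- rbind(
    mk("m03", "left", 0.02), mk("m03", "right", 0.02),
    mk("c", "left", 0.05), mk("c", "right", 0.05),
    mk("m01", "left", 0.2), mk("m01", "right", 0.2),
    mk("m02", "left", 0.1), mk("m02", "right", 0.1),
    mk("w", "left", 0.05), mk("w", "right", 0.05)
  )
  rep <- per_trial_report(cyc)
  expect_identical(
    unique(rep$trial), c("c", "m01", "m02", "m03", "w")
  )
  # variance declines across the motorized trials (adaptation pattern)
  v <- tapply(rep$gct_variance, rep$trial, mean)
  expect_true(v[["m01"]] > v[["m02"]] && v[["m02"]] > v[["m03"]])
})

test_that("a side missing from a trial is omitted with a warning", {
  cyc <- data.frame(trial = "m01", side = "left", gct = rnorm(5, 1.4, 0.1))
  expect_warning(rep <- per_trial_report(cyc), "right")
  expect_equal(nrow(rep), 1)
})
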