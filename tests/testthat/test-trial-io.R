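toy_trial <- function(n = 3, fs = 100) {
  m <- cbind(
    x = seq_len(n) / 10, y = rep(0, n),
    z = sin(seq_len(n) / 5) + 1
  )
  gait_trial(
    time = (seq_len(n) - 1) / fs,
    markers = list(
      left_heel = m, right_heel = m + 1, left_toe = m + 2, right_toe = m + 3
    ),
    sampling_rate = fs, condition_label = "c",
    trial_id = "t1", subject_id = "s1"
  )
}

test_that("a toy wide-schema file parses with its metadata", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(toy_trial(), p)
  tr <- read_trial_csv(p)
  expect_s3_class(tr, "gait_trial")
  expect_length(tr$time, 3)
  expect_equal(tr$sampling_rate, 100)
  expect_identical(tr$condition_label, "c")
  expect_identical(tr$trial_id, "t1")
})

test_that("a file missing a required marker fails naming it", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(toy_trial(), p)
  txt <- readLines(p)
  txt <- gsub("right_toe", "spare", txt)
  writeLines(txt, p)
  expect_error(read_trial_csv(p), "right_toe", class = "gaitmark_schema_error")
})

test_that("write -> read round-trips any valid trial at declared precision", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(50:200, 1)
    mk <- function() {
      cbind(x = rnorm(n, 0, 50), y = rnorm(n), z = abs(rnorm(n, 10, 5)))
    }
    tr <- gait_trial(
      time = (seq_len(n) - 1) / 100,
      markers = list(
        left_heel = mk(), right_heel = mk(), left_toe = mk(), right_toe = mk()
      ),
      sampling_rate = 100, condition_label = sample(c("c", "mm", "w"), 1),
      turn_window = if (seed == 2) c(0.1, 0.2) else NULL
    )
    p <- withr::local_tempfile(fileext = ".csv")
    write_trial_csv(tr, p)
    back <- read_trial_csv(p)
    for (m in names(tr$markers)) {
      expect_equal(back$markers[[m]], tr$markers[[m]], tolerance = 1e-8)
    }
    expect_equal(back$turn_window, tr$turn_window)
  }
})

test_that("files declaring mm are converted to cm on read", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(toy_trial(), p)
  txt <- sub("# units: cm", "# units: mm", readLines(p))
  writeLines(txt, p)
  tr <- read_trial_csv(p)
  expect_equal(
    tr$markers$left_heel[2, "z"], (sin(2 / 5) + 1) / 10,
    ignore_attr = TRUE, tolerance = 1e-8
  )
})

test_that("non-uniform timestamps beyond 1% of the period are rejected", {
  p <- withr::local_tempfile(fileext = ".csv")
  tr <- toy_trial(n = 10)
  tr$time[5] <- tr$time[5] + 0.002 # 20% of a 10 ms period
  write_trial_csv(tr, p)
  expect_error(read_trial_csv(p), "non-uniform", class = "gaitmark_timing_error")
})

test_that("an empty trial cannot be written", {
  tr <- toy_trial()
  tr$time <- numeric(0)
  tr$markers <- lapply(tr$markers, function(m) m[0, , drop = FALSE])
  expect_error(
    write_trial_csv(tr, tempfile()), "no samples",
    class = "gaitmark_schema_error"
  )
})

test_that("short marker gaps are linearly interpolated, long ones exclude", {
  tr <- toy_trial(n = 100)
  tr$markers$left_heel[40:44, "z"] <- NA # 5-sample gap
  v <- validate_trial(tr, max_gap = 10)
  expect_identical(v$verdict, "keep")
  # hand-computed linear fill between samples 39 and 45
  z39 <- tr$markers$left_heel[39, "z"]
  z45 <- tr$markers$left_heel[45, "z"]
  expect_equal(
    v$trial$markers$left_heel[40:44, "z"],
    z39 + (1:5) / 6 * (z45 - z39),
    ignore_attr = TRUE, tolerance = 1e-12
  )

  tr2 <- toy_trial(n = 100)
  tr2$markers$left_heel[20:69, "x"] <- NA # 50-sample gap
  v2 <- validate_trial(tr2, max_gap = 10)
  expect_identical(v2$verdict, "exclude")
  expect_null(v2$trial)

  v3 <- validate_trial(toy_trial(n = 100))
  expect_identical(v3$verdict, "keep")
  expect_true(all(v3$report$n_gaps == 0))
})
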