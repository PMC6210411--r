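# Shared fixtures: everything is generated in code at test time.

quiet_scenario <- function(...) {
  gait_scenario(noise_sd = 0, ...)
}

# a small noiseless simulation used across files
small_sim <- function(n = 5, seed = 11, ...) {
  generate_trial(quiet_scenario(n_cycles_per_side = n, seed = seed, ...))
}

# random extremum candidate sets for alternation property tests
random_candidates <- function(n, seed) {
  set.seed(seed)
  data.frame(
    kind = sample(c("peak", "valley"), n, replace = TRUE),
    time = sort(stats::runif(n, 0, 30)),
    height = stats::runif(n, 0, 25)
  )
}

# does an event series satisfy the alternation invariant?
expect_alternating <- function(ev) {
  k <- ev$events$kind
  expect_true(all(diff(ev$events$time) > 0))
  expect_identical(k[1], "valley")
  expect_identical(k[length(k)], "valley")
  expect_true(all(k[-1] != k[-length(k)]))
  pk <- which(k == "peak")
  expect_true(all(ev$events$height[pk] > ev$events$height[pk - 1]))
  expect_true(all(ev$events$height[pk] > ev$events$height[pk + 1]))
}

# build a gait_events object directly from an alternating event table
events_from_df <- function(df) {
  enforce_alternation(df)
}
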