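#' Generate a synthetic marker trial with known ground truth
#'
#' Simulates bilateral heel and toe marker trajectories for one walking
#' trial. Per side, the vertical heel signal is a smooth raised-cosine wave
#' with one valley (heel strike) and one peak per gait cycle; the vertical
#' toe signal has its valley (foot flat) `ids_fraction * GCT` after the
#' side's heel strike; the horizontal heel position advances by the side's
#' step length along a smooth monotone ramp during swing. Left and right are
#' phase-offset by half a cycle. If the scenario defines a turning segment,
#' the walking heading rotates 90 degrees across it while vertical cycling
#' continues, which exercises the turning-phase exclusion logic downstream.
#' Gaussian noise of standard deviation `noise_sd` is added independently to
#' every coordinate. The same scenario (including seed) always yields a
#' bit-identical trial.
#'
#' @param scenario a [gait_scenario()].
#' @param condition_label condition code attached to the trial, one of
#'   `"c"`, `"ml"`, `"mm"`, `"mh"`, `"w"` (unassisted, motorized walker at
#'   low/medium/high speed cue, conventional walker).
#' @param trial_id,subject_id identifier strings carried into outputs.
#'
#' @return A list with components:
#'   \describe{
#'     \item{trial}{a [gait_trial()] with markers `left_heel`, `right_heel`,
#'       `left_toe`, `right_toe` (cm, z vertical, x forward).}
#'     \item{truth}{a `gait_ground_truth` holding per-side heel-strike,
#'       heel-peak and toe-valley times plus the generating values; pass it
#'       to [ground_truth_parameters()] for per-cycle oracle records.}
#'   }
#' @export
#' @examples
#' sim <- generate_trial(gait_scenario(noise_sd = 0, seed = 7))
#' sim$trial
#' head(ground_truth_parameters(sim$truth))
generate_trial <- function(scenario, condition_label = "c",
                           trial_id = "t01", subject_id = "s01") {
  validate_scenario(scenario)
  sc <- scenario
  fs <- sc$sampling_rate
  n <- sc$n_cycles_per_side

  t0_left <- 0.15 * sc$gct_left + 0.3
  t0_right <- t0_left + sc$gct_right / 2
  gct_max <- max(sc$gct_left, sc$gct_right)
  t_end <- max(t0_left + n * sc$gct_left, t0_right + n * sc$gct_right) +
    max(0.45 * gct_max, 0.35)
  time <- seq(0, t_end, by = 1 / fs)
  psi <- heading_angle(time, sc$turn_start, sc$turn_duration)

  side_signals <- function(side, t0, lateral) {
    gct <- sc[[paste0("gct_", side)]]
    sw <- sc[[paste0("swing_fraction_", side)]] * gct
    st <- gct - sw
    sh <- sc[[paste0("step_height_", side)]]
    sl <- sc[[paste0("step_length_", side)]]
    ids <- sc$ids_fraction * gct

    phi <- time - t0
    heel_z <- cycle_wave(phi, gct, st, sh)
    rise_toe <- gct - ids - 0.3 * sw
    toe_z <- cycle_wave(phi - ids, gct, rise_toe, sc$toe_height)
    s <- progression_wave(phi, gct, st, sl)
    heel_xy <- path_from_progression(s, psi, lateral)
    toe_xy <- path_from_progression(s + 15, psi, lateral)

    edge <- 0.3
    tv <- t0 + (0:ceiling((t_end - t0) / gct)) * gct
    tv <- tv[tv >= edge & tv <= t_end - edge]
    n_cyc <- length(tv) - 1L
    gm_assert(n_cyc >= 1L, "scenario generates no complete gait cycle")
    k <- seq_len(n_cyc)
    truth <- list(
      heel_valley_times = tv,
      heel_peak_times = tv[k] + st,
      toe_valley_times = tv[k] + ids,
      heel_valley_heights = rep(0, length(tv)),
      heel_peak_heights = rep(sh, n_cyc),
      x_at_peaks = progression_wave(tv[k] + st - t0, gct, st, sl),
      gct = gct, sw = sw, st = st, ids = ids, sh = sh, sl = sl
    )
    list(
      heel = cbind(x = heel_xy$x, y = heel_xy$y, z = heel_z),
      toe = cbind(x = toe_xy$x, y = toe_xy$y, z = toe_z),
      truth = truth
    )
  }

  left <- side_signals("left", t0_left, 5)
  right <- side_signals("right", t0_right, -5)

  markers <- list(
    left_heel = left$heel, right_heel = right$heel,
    left_toe = left$toe, right_toe = right$toe
  )
  if (sc$noise_sd > 0) {
    markers <- with_preserved_seed(sc$seed, {
      lapply(markers, function(m) {
        m + matrix(stats::rnorm(length(m), 0, sc$noise_sd), nrow = nrow(m))
      })
    })
  }

  turn_window <- if (!is.null(sc$turn_start)) {
    c(sc$turn_start, sc$turn_start + sc$turn_duration)
  }
  trial <- gait_trial(
    time = time, markers = markers, sampling_rate = fs,
    condition_label = condition_label, trial_id = trial_id,
    subject_id = subject_id, turn_window = turn_window
  )
  truth <- structure(
    list(
      left = left$truth, right = right$truth,
      scenario = sc, duration = t_end
    ),
    class = "gait_ground_truth"
  )
  list(trial = trial, truth = truth)
}

#' @export
print.gait_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<gait_ground_truth> %d left / %d right cycles over %.1f s\n",
    length(x$left$heel_peak_times), length(x$right$heel_peak_times),
    x$duration
  ))
  invisible(x)
}

#' Per-cycle oracle records from generator ground truth
#'
#' Applies the event-time parameter definitions (cycle time as the interval
#' between consecutive heel-z valleys, swing as peak to next valley, stance
#' as their difference, double supports from the toe-flat valley, step
#' height from event heights, step length from the forward heel position at
#' consecutive peaks) directly to the generator's recorded event times. The
#' result is the reference against which the detection-based pipeline is
#' validated.
#'
#' @param gt a `gait_ground_truth` from [generate_trial()].
#' @return A data frame with one row per cycle and side: columns `side`,
#'   `k`, `gct`, `sw`, `st`, `ids`, `tds`, `sh`, `sl`, `vel` (first cycle of
#'   each side has `sl`/`vel` `NA`: no preceding peak).
#' @export
ground_truth_parameters <- function(gt) {
  gm_assert(
    inherits(gt, "gait_ground_truth"),
    "'gt' must be a gait_ground_truth object"
  )
  one_side <- function(side) {
    s <- gt[[side]]
    tv <- s$heel_valley_times
    n <- length(tv) - 1L
    if (n < 1L) {
      gm_stop(
        sprintf("no complete gait cycle on the %s side", side),
        "gaitmark_insufficient_cycles"
      )
    }
    k <- seq_len(n)
    gct <- tv[k + 1L] - tv[k]
    sw <- tv[k + 1L] - s$heel_peak_times[k]
    st <- gct - sw
    ids <- s$toe_valley_times[k] - tv[k]
    tds <- s$heel_peak_times[k] - s$toe_valley_times[k]
    sh <- s$heel_peak_heights[k] - s$heel_valley_heights[k]
    sl <- c(NA_real_, diff(s$x_at_peaks))
    data.frame(
      side = side, k = k, gct = gct, sw = sw, st = st,
      ids = ids, tds = tds, sh = sh, sl = sl, vel = sl / gct
    )
  }
  out <- rbind(one_side("left"), one_side("right"))
  rownames(out) <- NULL
  out
}
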