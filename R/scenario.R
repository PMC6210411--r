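#' Define a synthetic walking scenario
#'
#' A scenario fixes the generative gait parameters for one simulated walking
#' trial: per-side gait cycle time, swing fraction, double-support fractions,
#' step height and length, marker noise, and an optional 90-degree turning
#' segment. The defaults correspond to unassisted parkinsonian walking as
#' reported in group summaries of six-subject walker studies (cycle time
#' around 1.3 s, swing around 27% of the cycle, initial double support around
#' 19%, step height around 21 cm, step length around 93 cm) with 0.2 cm
#' additive marker noise at a 100 Hz capture rate.
#'
#' Stance must contain both double-support phases plus a single-support
#' interval, so `swing_fraction + ids_fraction + tds_fraction < 1` is
#' enforced per side. Note that the per-foot event formulas tie terminal
#' double support to `stance - IDS`; `tds_fraction` therefore only enters
#' this feasibility constraint (see the methods vignette).
#'
#' @param sampling_rate capture rate in Hz.
#' @param n_cycles_per_side number of complete gait cycles generated per foot.
#' @param gct_left,gct_right gait cycle time per side, seconds.
#' @param swing_fraction_left,swing_fraction_right swing time as a fraction of
#'   the side's gait cycle time, in (0, 1).
#' @param ids_fraction initial double support as a fraction of the gait cycle
#'   time (toe-flat delay after heel strike), in (0, 1).
#' @param tds_fraction terminal double support fraction, in (0, 1); used in
#'   the stance feasibility invariant.
#' @param step_height_left,step_height_right vertical heel excursion per
#'   cycle, cm.
#' @param step_length_left,step_length_right forward heel displacement per
#'   cycle, cm.
#' @param noise_sd standard deviation of additive i.i.d. Gaussian noise on
#'   every marker coordinate, cm. Zero gives a noiseless trial.
#' @param toe_height vertical toe excursion per cycle, cm. Any positive value
#'   gives a unique toe-flat valley per cycle; the default is a typical toe
#'   marker clearance.
#' @param turn_start,turn_duration optional start time and duration (s) of a
#'   90-degree heading rotation; both `NULL` for straight walking.
#' @param seed integer seed; identical scenarios generate bit-identical
#'   trials.
#'
#' @return An object of class `gait_scenario`.
#' @seealso [generate_trial()]
#' @export
#' @examples
#' gait_scenario(gct_left = 1.0, gct_right = 0.9, noise_sd = 0)
gait_scenario <- function(sampling_rate = 100,
                          n_cycles_per_side = 12,
                          gct_left = 1.29,
                          gct_right = 1.29,
                          swing_fraction_left = 0.27,
                          swing_fraction_right = 0.27,
                          ids_fraction = 0.1875,
                          tds_fraction = 0.1688,
                          step_height_left = 21.2,
                          step_height_right = 21.2,
                          step_length_left = 93,
                          step_length_right = 93,
                          noise_sd = 0.2,
                          toe_height = 6,
                          turn_start = NULL,
                          turn_duration = NULL,
                          seed = 1L) {
  sc <- list(
    sampling_rate = sampling_rate,
    n_cycles_per_side = as.integer(n_cycles_per_side),
    gct_left = gct_left, gct_right = gct_right,
    swing_fraction_left = swing_fraction_left,
    swing_fraction_right = swing_fraction_right,
    ids_fraction = ids_fraction,
    tds_fraction = tds_fraction,
    step_height_left = step_height_left,
    step_height_right = step_height_right,
    step_length_left = step_length_left,
    step_length_right = step_length_right,
    noise_sd = noise_sd,
    toe_height = toe_height,
    turn_start = turn_start,
    turn_duration = turn_duration,
    seed = as.integer(seed)
  )
  class(sc) <- "gait_scenario"
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  pos <- c(
    "sampling_rate", "n_cycles_per_side", "gct_left", "gct_right",
    "step_height_left", "step_height_right",
    "step_length_left", "step_length_right", "toe_height"
  )
  for (f in pos) {
    v <- sc[[f]]
    gm_assert(
      is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0,
      sprintf("scenario field '%s' must be a single positive number", f)
    )
  }
  frac <- c(
    "swing_fraction_left", "swing_fraction_right",
    "ids_fraction", "tds_fraction"
  )
  for (f in frac) {
    v <- sc[[f]]
    gm_assert(
      is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0 && v < 1,
      sprintf("scenario field '%s' must lie strictly in (0, 1)", f)
    )
  }
  gm_assert(
    is.numeric(sc$noise_sd) && length(sc$noise_sd) == 1L &&
      is.finite(sc$noise_sd) && sc$noise_sd >= 0,
    "scenario field 'noise_sd' must be a single nonnegative number"
  )
  for (side in c("left", "right")) {
    s <- sc[[paste0("swing_fraction_", side)]]
    tot <- s + sc$ids_fraction + sc$tds_fraction
    gm_assert(
      tot < 1,
      sprintf(
        paste0(
          "scenario fields 'swing_fraction_%s' + 'ids_fraction' + ",
          "'tds_fraction' must sum below 1 (stance must contain both ",
          "double supports plus single support); got %.3f"
        ),
        side, tot
      )
    )
  }
  if (!is.null(sc$turn_start) || !is.null(sc$turn_duration)) {
    gm_assert(
      !is.null(sc$turn_start) && !is.null(sc$turn_duration),
      "scenario fields 'turn_start' and 'turn_duration' must be set together"
    )
    gm_assert(
      is.numeric(sc$turn_start) && sc$turn_start > 0,
      "scenario field 'turn_start' must be a positive time in seconds"
    )
    gm_assert(
      is.numeric(sc$turn_duration) && sc$turn_duration > 0,
      "scenario field 'turn_duration' must be a positive duration in seconds"
    )
  }
  gm_assert(
    is.numeric(sc$seed) && length(sc$seed) == 1L && is.finite(sc$seed),
    "scenario field 'seed' must be a single integer"
  )
  invisible(sc)
}

#' @export
print.gait_scenario <- function(x, ...) {
  cat("<gait_scenario>\n")
  cat(sprintf(
    "  %d cycles/side at %g Hz, seed %d\n",
    x$n_cycles_per_side, x$sampling_rate, x$seed
  ))
  cat(sprintf(
    "  GCT L/R: %.3f/%.3f s, swing: %.2f/%.2f, IDS: %.3f, TDS: %.3f\n",
    x$gct_left, x$gct_right, x$swing_fraction_left, x$swing_fraction_right,
    x$ids_fraction, x$tds_fraction
  ))
  cat(sprintf(
    "  SH L/R: %.1f/%.1f cm, SL L/R: %.1f/%.1f cm, noise %.2f cm\n",
    x$step_height_left, x$step_height_right,
    x$step_length_left, x$step_length_right, x$noise_sd
  ))
  if (!is.null(x$turn_start)) {
    cat(sprintf(
      "  turn: %.2f s + %.2f s\n", x$turn_start, x$turn_duration
    ))
  }
  invisible(x)
}

#' Read a scenario from a YAML configuration file
#'
#' Keys are exactly the [gait_scenario()] arguments; missing keys take the
#' defaults.
#'
#' @param path path to a YAML file.
#' @return A `gait_scenario`.
#' @export
read_scenario <- function(path) {
  gm_assert(
    file.exists(path), sprintf("scenario file '%s' does not exist", path),
    "gaitmark_io_error"
  )
  keys <- yaml::read_yaml(path)
  known <- names(formals(gait_scenario))
  bad <- setdiff(names(keys), known)
  gm_assert(
    length(bad) == 0L,
    sprintf("unknown scenario field(s): %s", paste(bad, collapse = ", "))
  )
  do.call(gait_scenario, keys)
}
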