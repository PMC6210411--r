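# Per-cycle spatiotemporal gait parameters and condition-level summaries.
#
# For cycle k delimited by heel-z valleys at tV(k-1), tV(k) with the
# intervening peak at tP(k):
#   GCT = tV(k) - tV(k-1)          cycle time
#   SW  = tV(k) - tP(k)            swing (peak to next valley)
#   ST  = GCT - SW                 stance
#   IDS = tVto - tV(k-1)           initial double support (toe-flat delay)
#   TDS = tP(k) - tVto             terminal double support
#   SH  = zP(k) - zV(k-1)          step height (event heights)
#   SL  = x(tP(k)) - x(tP(k-1))    step length (forward heel position at
#                                  consecutive peaks; first cycle has none)
#   Vel = SL / GCT
# Time-like symbols are event times; SH reads the event heights.

#' Extraction configuration
#'
#' Bundles the tunable knobs of the event-extraction chain. Defaults are
#' chosen for 100 Hz capture: a 0.4 s Hanning window, a 2 cm prominence
#' floor (well below the smallest plausible step height), a 10-sample
#' extremum neighborhood, and a 4-sample parabolic refinement window.
#'
#' @param smoothing a [smoothing_config()].
#' @param min_prominence_cm extremum prominence floor, cm.
#' @param neighborhood_samples local-extremum half-window, samples.
#' @param refine_halfwidth,refine_iterations raw-signal parabolic
#'   refinement window (samples) and re-centering passes.
#' @param max_gap largest marker gap repaired by [validate_trial()].
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(smoothing = smoothing_config(),
                              min_prominence_cm = 2,
                              neighborhood_samples = 10,
                              refine_halfwidth = 4,
                              refine_iterations = 2,
                              max_gap = 10) {
  structure(
    list(
      smoothing = smoothing,
      min_prominence_cm = min_prominence_cm,
      neighborhood_samples = neighborhood_samples,
      refine_halfwidth = refine_halfwidth,
      refine_iterations = refine_iterations,
      max_gap = max_gap
    ),
    class = "extraction_config"
  )
}

# forward heel position at a (possibly sub-sample) event time, read as a
# short local mean so single-sample noise does not propagate into SL
x_at_time <- function(x, t, fs, halfwidth = 3L) {
  i <- round(t * fs) + 1L
  lo <- max(1L, i - halfwidth)
  hi <- min(length(x), i + halfwidth)
  mean(x[lo:hi])
}

#' Compute per-cycle gait parameters from an event series
#'
#' @param events a `gait_events` object (ideally refined); only `kept`
#'   cycles with a unique intervening peak produce records.
#' @param toe_valleys optional `toe_valley_set` from [match_toe_valleys()];
#'   without it IDS/TDS are `NA`.
#' @param heel_x optional raw forward heel position (cm) sampled at `fs`,
#'   for SL and velocity.
#' @param fs sampling rate, Hz.
#' @return A data frame of class `gait_cycles`, one row per kept cycle:
#'   `k`, `gct`, `sw`, `st`, `ids`, `tds`, `sh`, `sl`, `vel`, `valid`.
#'   `valid` is `FALSE` when event mis-ordering produced a negative
#'   duration; such cycles are flagged, never silently clamped. `sl`/`vel`
#'   need the previous cycle's peak, so the first kept cycle of a contiguous
#'   run has them `NA`.
#' @export
compute_cycles <- function(events, toe_valleys = NULL, heel_x = NULL, fs) {
  gm_assert(inherits(events, "gait_events"), "'events' must be gait_events")
  cyc <- events$cycles[events$cycles$kept & !is.na(events$cycles$t_peak), ,
    drop = FALSE
  ]
  if (nrow(cyc) == 0L) {
    gm_stop(
      "insufficient cycles: no kept cycle with a unique peak",
      "gaitmark_insufficient_cycles"
    )
  }
  toe <- rep(NA_real_, nrow(cyc))
  if (!is.null(toe_valleys)) {
    m <- match(cyc$k, toe_valleys$k)
    toe <- toe_valleys$t_toe[m]
  }
  gct <- cyc$t_end - cyc$t_start
  sw <- cyc$t_end - cyc$t_peak
  st <- gct - sw
  ids <- toe - cyc$t_start
  tds <- cyc$t_peak - toe
  sh <- cyc$h_peak - cyc$h_start
  sl <- rep(NA_real_, nrow(cyc))
  if (!is.null(heel_x)) {
    xp <- vapply(cyc$t_peak, function(t) x_at_time(heel_x, t, fs), numeric(1))
    prev <- match(cyc$k - 1L, cyc$k) # previous cycle must be contiguous
    sl <- xp - xp[prev]
  }
  valid <- gct > 0 & sw >= 0 & st >= 0 &
    (is.na(ids) | ids >= 0) & (is.na(tds) | tds >= 0)
  out <- data.frame(
    k = cyc$k, gct = gct, sw = sw, st = st, ids = ids, tds = tds,
    sh = sh, sl = sl, vel = sl / gct, valid = valid
  )
  rownames(out) <- NULL
  class(out) <- c("gait_cycles", "data.frame")
  out
}

#' Extract gait cycles from a trial, end to end
#'
#' Runs the full chain for both feet of one trial: smooth the vertical heel
#' and toe signals, detect extremum candidates, enforce peak/valley
#' alternation, refine events on the raw signals, exclude turning-phase
#' cycles, assign toe-flat valleys, and compute the per-cycle parameters.
#'
#' @param trial a [gait_trial()].
#' @param config an [extraction_config()].
#' @return A data frame with one row per extracted cycle, adding `side`,
#'   `subject`, `trial`, `condition` to the [compute_cycles()] columns. An
#'   `accounting` attribute counts detected / turn-excluded / flagged
#'   cycles per side.
#' @export
extract_cycles <- function(trial, config = extraction_config()) {
  gm_assert(inherits(trial, "gait_trial"), "'trial' must be a gait_trial")
  fs <- trial$sampling_rate
  out <- list()
  acct <- list()
  for (side in c("left", "right")) {
    heel <- trial$markers[[paste0(side, "_heel")]]
    toe <- trial$markers[[paste0(side, "_toe")]]
    heel_z_s <- smooth_signal(heel[, "z"], fs, config$smoothing)
    toe_z_s <- smooth_signal(toe[, "z"], fs, config$smoothing)
    ev <- detect_extrema(
      heel_z_s, fs, config$min_prominence_cm, config$neighborhood_samples
    )
    ev <- enforce_alternation(ev)
    ev <- refine_events(
      ev, heel[, "z"], fs, config$refine_halfwidth, config$refine_iterations
    )
    n_detected <- nrow(ev$cycles)
    ev <- exclude_turn_window(ev, trial$turn_window)
    n_turn <- sum(!ev$cycles$kept)
    toe_v <- match_toe_valleys(
      ev, toe_z_s, fs,
      toe_z_raw = toe[, "z"],
      min_prominence = min(config$min_prominence_cm, 1),
      neighborhood = config$neighborhood_samples,
      halfwidth = config$refine_halfwidth,
      iterations = config$refine_iterations
    )
    cyc <- compute_cycles(ev, toe_v, heel[, "x"], fs)
    kept <- ev$cycles[ev$cycles$kept & !is.na(ev$cycles$t_peak), , drop = FALSE]
    cyc <- cbind(side = side, cyc)
    attr(cyc, "t_start") <- data.frame(
      side = side, k = kept$k, t_start = kept$t_start
    )
    out[[side]] <- cyc
    acct[[side]] <- data.frame(
      side = side, detected = n_detected, turn_excluded = n_turn,
      flagged_invalid = sum(!cyc$valid), used = sum(cyc$valid)
    )
  }
  times <- do.call(rbind, lapply(out, attr, "t_start"))
  res <- do.call(rbind, out)
  res$subject <- trial$subject_id
  res$trial <- trial$trial_id
  res$condition <- trial$condition_label
  rownames(res) <- rownames(times) <- NULL
  attr(res, "accounting") <- do.call(rbind, acct)
  attr(res, "times") <- times
  class(res) <- c("gait_cycles", "data.frame")
  res
}

#' Summarize gait parameters for one condition
#'
#' Mean and sample standard deviation of each per-cycle parameter plus the
#' support-phase ratios. Ratios are computed from parameter means
#' (`mean(phase) / mean(GCT) * 100`), and the condition velocity is the
#' mean of per-cycle velocities — the convention under which summary tables
#' are internally consistent.
#'
#' @param records a `gait_cycles` data frame (rows with `valid = FALSE` are
#'   dropped with a message).
#' @param label condition label stored in the summary.
#' @return An object of class `condition_summary`: list with `label`,
#'   `parameters` (parameter, mean, sd, n) and `ratios` (ratio, value_pct).
#' @export
summarize_condition <- function(records, label = NA_character_) {
  gm_assert(is.data.frame(records), "'records' must be a data frame")
  if (nrow(records) == 0L) {
    gm_stop("insufficient cycles: no records", "gaitmark_insufficient_cycles")
  }
  if ("valid" %in% names(records) && any(!records$valid)) {
    message(sprintf("dropping %d invalid cycle(s)", sum(!records$valid)))
    records <- records[records$valid, , drop = FALSE]
    if (nrow(records) == 0L) {
      gm_stop(
        "insufficient cycles: all records invalid",
        "gaitmark_insufficient_cycles"
      )
    }
  }
  params <- c("gct", "sw", "st", "ids", "tds", "sl", "sh", "vel")
  stats_df <- do.call(rbind, lapply(params, function(p) {
    v <- records[[p]]
    v <- v[!is.na(v)]
    data.frame(
      parameter = p,
      mean = if (length(v) > 0L) mean(v) else NA_real_,
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
      n = length(v)
    )
  }))
  m <- function(p) stats_df$mean[stats_df$parameter == p]
  ratios <- data.frame(
    ratio = c("st_gct", "ids_gct", "tds_gct", "ids_st", "tds_st"),
    value_pct = 100 * c(
      m("st") / m("gct"), m("ids") / m("gct"), m("tds") / m("gct"),
      m("ids") / m("st"), m("tds") / m("st")
    )
  )
  structure(
    list(label = label, parameters = stats_df, ratios = ratios),
    class = "condition_summary"
  )
}

#' @export
print.condition_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<condition_summary> %s\n", x$label))
  df <- x$parameters
  df$mean <- round(df$mean, digits)
  df$sd <- round(df$sd, digits)
  print(df, row.names = FALSE)
  r <- x$ratios
  r$value_pct <- round(r$value_pct, 2)
  print(r, row.names = FALSE)
  invisible(x)
}

#' Summarize every condition in a cycle table
#'
#' @param cycles a `gait_cycles` data frame with a `condition` column.
#' @return Named list of [summarize_condition()] results.
#' @export
summarize_conditions <- function(cycles) {
  gm_assert(
    "condition" %in% names(cycles),
    "'cycles' needs a 'condition' column"
  )
  labs <- unique(cycles$condition)
  stats::setNames(
    lapply(labs, function(l) {
      summarize_condition(cycles[cycles$condition == l, , drop = FALSE], l)
    }),
    labs
  )
}

#' Long-format parameter and ratio tables from condition summaries
#'
#' @param summaries a list of `condition_summary` objects.
#' @return `parameter_table()`: data frame `parameter`, `condition`, `mean`,
#'   `sd`, `n`. `ratio_table()`: data frame `ratio`, `condition`,
#'   `value_pct`.
#' @export
parameter_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    cbind(s$parameters, condition = s$label)
  }))
}

#' @rdname parameter_table
#' @export
ratio_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    cbind(s$ratios, condition = s$label)
  }))
}
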