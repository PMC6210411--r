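# Gait event detection on the smoothed vertical heel signal: candidate
# extrema -> alternation enforcement -> raw-signal refinement ->
# turning-phase exclusion -> per-cycle toe-valley assignment.

# Running max/min over a +/- nb sample neighborhood, via shifted pmax/pmin.
running_extreme <- function(z, nb, maximum = TRUE) {
  n <- length(z)
  out <- z
  f <- if (maximum) pmax else pmin
  pad <- if (maximum) -Inf else Inf
  for (k in seq_len(nb)) {
    out <- f(out, c(z[-seq_len(k)], rep(pad, k)))
    out <- f(out, c(rep(pad, k), z[seq_len(n - k)]))
  }
  out
}

# Topographic prominence of the extremum at index i: height above (below)
# the higher (lower) of the two key saddles toward the nearest taller
# (deeper) extremum on each side, as in standard peak-finding toolboxes.
extremum_prominence <- function(z, i, maximum = TRUE) {
  s <- if (maximum) z else -z
  n <- length(s)
  left <- if (i > 1L) {
    seg <- s[(i - 1L):1L]
    stop_at <- which(seg > s[i])[1]
    if (is.na(stop_at)) min(seg) else min(seg[seq_len(stop_at)])
  } else {
    s[i]
  }
  right <- if (i < n) {
    seg <- s[(i + 1L):n]
    stop_at <- which(seg > s[i])[1]
    if (is.na(stop_at)) min(seg) else min(seg[seq_len(stop_at)])
  } else {
    s[i]
  }
  s[i] - max(left, right)
}

#' Detect peak and valley candidates on a smoothed signal
#'
#' Returns every local maximum and minimum of `z` over a `+/- neighborhood`
#' sample window whose topographic prominence is at least `min_prominence`.
#' Plateau extrema are resolved to their first sample. The candidates are
#' raw material for [enforce_alternation()], which applies the
#' one-peak-between-valleys rule.
#'
#' @param z smoothed vertical marker signal, cm.
#' @param fs sampling rate, Hz.
#' @param min_prominence minimum extremum prominence in cm (default 2, far
#'   below any plausible step height and above smoothed marker noise).
#' @param neighborhood half-width in samples of the local-extremum window
#'   (default 10).
#' @return A data frame of candidates: `kind` (`"peak"`/`"valley"`), `time`
#'   (s), `height` (cm), `index` (1-based sample).
#' @export
detect_extrema <- function(z, fs, min_prominence = 2, neighborhood = 10) {
  gm_assert(is.numeric(z) && length(z) > 2L, "'z' must be a numeric signal")
  gm_assert(min_prominence >= 0, "'min_prominence' must be >= 0")
  nb <- as.integer(neighborhood)
  gm_assert(nb >= 1L, "'neighborhood' must be >= 1 sample")
  n <- length(z)
  hi <- running_extreme(z, nb, TRUE)
  lo <- running_extreme(z, nb, FALSE)
  is_pk <- z >= hi & hi > lo & c(-Inf, z[-n]) < z
  is_vl <- z <= lo & hi > lo & c(Inf, z[-n]) > z
  # windows truncated by the signal edge cannot certify an extremum
  edge <- c(seq_len(min(nb, n)), seq(max(n - nb + 1L, 1L), n))
  is_pk[edge] <- FALSE
  is_vl[edge] <- FALSE
  idx <- sort(c(which(is_pk), which(is_vl)))
  if (length(idx) > 0L) {
    kind <- ifelse(is_pk[idx], "peak", "valley")
    keep <- vapply(
      seq_along(idx),
      function(j) {
        extremum_prominence(z, idx[j], kind[j] == "peak") >= min_prominence
      },
      logical(1)
    )
    idx <- idx[keep]
    kind <- kind[keep]
  } else {
    kind <- character(0)
  }
  out <- data.frame(
    kind = kind, time = (idx - 1) / fs, height = z[idx], index = idx
  )
  if (sum(out$kind == "valley") < 2L) {
    gm_stop(
      "insufficient cycles: fewer than 2 valleys detected",
      "gaitmark_insufficient_cycles"
    )
  }
  out
}

#' Enforce peak/valley alternation
#'
#' Applies the selection rule that removes turning-phase detection errors:
#' between two consecutive valleys only the highest peak is kept, and
#' between two consecutive peaks only the lowest valley (ties keep the
#' earlier event), repeated until the series is strictly alternating with
#' every peak above its neighboring valleys (degenerate peak/valley pairs
#' that violate this are removed pairwise). Leading and trailing events are
#' trimmed so the series
#' starts and ends with a valley, i.e. covers complete cycles only. The
#' operation is idempotent.
#'
#' @param candidates data frame from [detect_extrema()] (columns `kind`,
#'   `time`, `height`, optionally `index`), sorted by time.
#' @return An object of class `gait_events`: list with `events` (the
#'   alternating series) and `cycles` (one row per cycle: valley-peak-valley
#'   triple with times and heights, plus a `kept` flag).
#' @export
enforce_alternation <- function(candidates) {
  ev <- as.data.frame(candidates)
  gm_assert(
    all(c("kind", "time", "height") %in% names(ev)),
    "'candidates' needs columns kind, time, height"
  )
  ev <- ev[order(ev$time), , drop = FALSE]
  # repeat run-collapsing + inverted-pair removal until the full invariant
  # (strict alternation, every peak above its neighboring valleys) holds
  repeat {
    if (nrow(ev) == 0L) break
    runs <- rle(ev$kind)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    pick <- integer(length(runs$lengths))
    for (r in seq_along(runs$lengths)) {
      rows <- starts[r]:ends[r]
      pick[r] <- if (runs$values[r] == "peak") {
        rows[which.max(ev$height[rows])]
      } else {
        rows[which.min(ev$height[rows])]
      }
    }
    ev <- ev[pick, , drop = FALSE]
    # a "peak" not rising above an adjacent "valley" is a non-monotone
    # wiggle, not a gait cycle: drop the offending pair and re-collapse
    bad <- integer(0)
    pk <- which(ev$kind == "peak")
    for (i in pk) {
      if (i > 1L && ev$height[i] <= ev$height[i - 1L]) {
        bad <- c(i, i - 1L)
        break
      }
      if (i < nrow(ev) && ev$height[i] <= ev$height[i + 1L]) {
        bad <- c(i, i + 1L)
        break
      }
    }
    if (length(bad) == 0L) break
    ev <- ev[-bad, , drop = FALSE]
  }
  # trim to valley ... valley
  vl <- which(ev$kind == "valley")
  if (length(vl) >= 1L) {
    ev <- ev[vl[1]:vl[length(vl)], , drop = FALSE]
  } else {
    ev <- ev[0, , drop = FALSE]
  }
  if (sum(ev$kind == "valley") < 2L) {
    gm_stop(
      "insufficient cycles: fewer than 2 valleys after alternation",
      "gaitmark_insufficient_cycles"
    )
  }
  rownames(ev) <- NULL
  new_gait_events(ev)
}

new_gait_events <- function(ev) {
  vl <- which(ev$kind == "valley")
  n_cyc <- length(vl) - 1L
  cycles <- data.frame(
    k = seq_len(n_cyc),
    t_start = ev$time[vl[-length(vl)]],
    t_peak = NA_real_, t_end = ev$time[vl[-1]],
    h_start = ev$height[vl[-length(vl)]],
    h_peak = NA_real_, h_end = ev$height[vl[-1]],
    kept = rep(TRUE, n_cyc),
    drop_reason = rep(NA_character_, n_cyc)
  )
  for (j in seq_len(n_cyc)) {
    between <- which(
      ev$kind == "peak" & ev$time > cycles$t_start[j] &
        ev$time < cycles$t_end[j]
    )
    if (length(between) == 1L) {
      cycles$t_peak[j] <- ev$time[between]
      cycles$h_peak[j] <- ev$height[between]
    }
  }
  structure(list(events = ev, cycles = cycles), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf(
    "<gait_events> %d events, %d cycles (%d kept)\n",
    nrow(x$events), nrow(x$cycles), sum(x$cycles$kept)
  ))
  invisible(x)
}

#' Refine event times and heights on the raw signal
#'
#' Smoothing-based detection locates each event to within a few samples but
#' carries a shape-dependent lag and attenuates extremum heights. This step
#' re-estimates each event by a least-squares parabola fit to the *raw*
#' signal in a `+/- halfwidth` sample window around the detected location,
#' iterated so the window re-centers on the fitted apex. Event times become
#' continuous (sub-sample) and heights amplitude-true.
#'
#' @param events a `gait_events` object from [enforce_alternation()].
#' @param z_raw the unsmoothed signal the events were detected on.
#' @param fs sampling rate, Hz.
#' @param halfwidth fit half-window in samples (default 4).
#' @param iterations re-centering passes (default 2).
#' @return The refined `gait_events` object.
#' @export
refine_events <- function(events, z_raw, fs, halfwidth = 4, iterations = 2) {
  gm_assert(inherits(events, "gait_events"), "'events' must be gait_events")
  ev <- events$events
  for (i in seq_len(nrow(ev))) {
    r <- parabolic_refine(
      z_raw, ev$time[i] * fs + 1, ev$kind[i] == "peak",
      halfwidth, iterations
    )
    ev$time[i] <- (r[["t"]] - 1) / fs
    ev$height[i] <- r[["h"]]
  }
  new_gait_events(ev)
}

parabolic_refine <- function(z, idx, maximum = TRUE,
                             halfwidth = 4, iterations = 2) {
  n <- length(z)
  # pre-center on the raw-signal extremum near the candidate: the smoothed
  # location can lag the true event by a few samples, which would leave the
  # fit window lopsided on the extremum's flank
  pre <- halfwidth + 5L
  lo <- max(1L, round(idx) - pre)
  hi <- min(n, round(idx) + pre)
  seg <- z[lo:hi]
  t0 <- lo + (if (maximum) which.max(seg) else which.min(seg)) - 1L
  best <- c(t = t0, h = z[t0])
  for (it in seq_len(iterations)) {
    c0 <- round(t0)
    lo <- max(1L, c0 - halfwidth)
    hi <- min(n, c0 + halfwidth)
    s <- (lo:hi) - c0
    fit <- stats::lm.fit(cbind(1, s, s^2), z[lo:hi])$coefficients
    # a fit curving the wrong way cannot locate this extremum; keep the
    # sample-level estimate
    wrong_sign <- if (maximum) fit[3] >= 0 else fit[3] <= 0
    if (!is.finite(fit[3]) || wrong_sign) {
      return(best)
    }
    dt <- -fit[2] / (2 * fit[3])
    dt <- max(min(dt, halfwidth), -halfwidth)
    t0 <- c0 + dt
    best <- c(t = t0, h = unname(fit[1] - fit[2]^2 / (4 * fit[3])))
  }
  best
}

#' Exclude cycles overlapping a turning window
#'
#' Drops every cycle whose `[valley, next valley]` interval overlaps the
#' window — cycles are removed whole, never truncated, so the retained
#' series still consists of complete straight-walking cycles.
#'
#' @param events a `gait_events` object.
#' @param turn_window numeric `c(start, end)` in seconds, or `NULL` for a
#'   no-op.
#' @return The `gait_events` object with overlapping cycles marked
#'   `kept = FALSE` (`drop_reason = "turn"`). May leave zero kept cycles;
#'   downstream extraction then reports insufficient cycles.
#' @export
exclude_turn_window <- function(events, turn_window) {
  gm_assert(inherits(events, "gait_events"), "'events' must be gait_events")
  if (is.null(turn_window)) {
    return(events)
  }
  gm_assert(
    is.numeric(turn_window) && length(turn_window) == 2L &&
      turn_window[1] < turn_window[2],
    "'turn_window' must be c(start, end) with start < end"
  )
  cyc <- events$cycles
  overlap <- cyc$t_start <= turn_window[2] & cyc$t_end >= turn_window[1]
  cyc$kept[overlap] <- FALSE
  cyc$drop_reason[overlap] <- "turn"
  events$cycles <- cyc
  events
}

#' Assign a toe-flat valley to each heel cycle
#'
#' For each kept cycle, the vertical toe signal's local minimum nearest in
#' time after the cycle's heel strike, searched within
#' `(valley, peak]`, is taken as the toe-flat event that anchors the
#' initial/terminal double-support split. Cycles without a toe valley in
#' that interval are flagged and get missing IDS/TDS downstream.
#'
#' @param events a `gait_events` object (refined or not).
#' @param toe_z smoothed vertical toe signal, same length and rate as the
#'   heel signal the events came from.
#' @param fs sampling rate, Hz.
#' @param toe_z_raw optional raw toe signal for parabolic refinement of the
#'   toe-valley times.
#' @param min_prominence,neighborhood passed to [detect_extrema()].
#' @param halfwidth,iterations passed to the raw-signal refinement.
#' @return A data frame (class `toe_valley_set`): `k`, `t_toe` (s, `NA` when
#'   missing), `flagged`.
#' @export
match_toe_valleys <- function(events, toe_z, fs, toe_z_raw = NULL,
                              min_prominence = 2, neighborhood = 10,
                              halfwidth = 4, iterations = 2) {
  gm_assert(inherits(events, "gait_events"), "'events' must be gait_events")
  cand <- tryCatch(
    detect_extrema(toe_z, fs, min_prominence, neighborhood),
    gaitmark_insufficient_cycles = function(e) NULL
  )
  t_valleys <- numeric(0)
  if (!is.null(cand)) {
    vl <- cand[cand$kind == "valley", , drop = FALSE]
    t_valleys <- vl$time
    if (!is.null(toe_z_raw) && nrow(vl) > 0L) {
      t_valleys <- vapply(
        vl$time * fs + 1,
        function(i) {
          r <- parabolic_refine(
            toe_z_raw, i,
            maximum = FALSE, halfwidth = halfwidth, iterations = iterations
          )
          (r[["t"]] - 1) / fs
        },
        numeric(1)
      )
    }
  }
  cyc <- events$cycles
  out <- data.frame(
    k = cyc$k, t_toe = NA_real_, flagged = TRUE
  )
  for (j in seq_len(nrow(cyc))) {
    if (is.na(cyc$t_peak[j])) next
    inside <- t_valleys[
      t_valleys > cyc$t_start[j] & t_valleys <= cyc$t_peak[j]
    ]
    if (length(inside) > 0L) {
      out$t_toe[j] <- inside[which.min(inside - cyc$t_start[j])]
      out$flagged[j] <- FALSE
    }
  }
  class(out) <- c("toe_valley_set", "data.frame")
  out
}
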