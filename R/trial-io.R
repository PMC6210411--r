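#' Construct a marker trial
#'
#' A `gait_trial` bundles the time-indexed 3D positions of the named markers
#' of one walking trial with its sampling rate and metadata. Coordinates are
#' in cm with z vertical (positive up) and x the nominal progression axis.
#' The four markers `left_heel`, `right_heel`, `left_toe`, `right_toe` are
#' required; additional markers are carried through untouched.
#'
#' @param time numeric vector of sample times in seconds.
#' @param markers named list of numeric matrices (or data frames) with
#'   columns `x`, `y`, `z`, one row per sample, positions in cm.
#' @param sampling_rate sampling rate in Hz.
#' @param condition_label condition code (`"c"`, `"ml"`, `"mm"`, `"mh"`,
#'   `"w"`), or `NA`.
#' @param trial_id,subject_id identifier strings.
#' @param turn_window optional numeric `c(start, end)` in seconds marking
#'   the turning segment to exclude from straight-walking analysis.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(time, markers, sampling_rate,
                       condition_label = NA_character_,
                       trial_id = "t01", subject_id = "s01",
                       turn_window = NULL) {
  gm_assert(
    is.numeric(sampling_rate) && length(sampling_rate) == 1L &&
      sampling_rate > 0,
    "'sampling_rate' must be a single positive number"
  )
  gm_assert(
    is.list(markers) && !is.null(names(markers)),
    "'markers' must be a named list", "gaitmark_schema_error"
  )
  missing <- setdiff(required_markers(), names(markers))
  if (length(missing) > 0L) {
    gm_stop(
      sprintf(
        "required marker(s) missing: %s", paste(missing, collapse = ", ")
      ),
      "gaitmark_schema_error"
    )
  }
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    gm_assert(
      all(c("x", "y", "z") %in% colnames(m)),
      "each marker needs columns x, y, z", "gaitmark_schema_error"
    )
    m[, c("x", "y", "z"), drop = FALSE]
  })
  lens <- vapply(markers, nrow, integer(1))
  gm_assert(
    length(unique(c(lens, length(time)))) == 1L,
    "all marker series and 'time' must have equal length",
    "gaitmark_schema_error"
  )
  gm_assert(length(time) > 0L, "trial has no samples", "gaitmark_schema_error")
  if (!is.null(turn_window)) {
    gm_assert(
      is.numeric(turn_window) && length(turn_window) == 2L &&
        turn_window[1] < turn_window[2],
      "'turn_window' must be c(start, end) with start < end"
    )
  }
  structure(
    list(
      time = as.numeric(time), markers = markers,
      sampling_rate = sampling_rate, condition_label = condition_label,
      trial_id = trial_id, subject_id = subject_id,
      turn_window = turn_window
    ),
    class = "gait_trial"
  )
}

required_markers <- function() {
  c("left_heel", "right_heel", "left_toe", "right_toe")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial> %s/%s [%s]: %d samples at %g Hz (%.1f s), markers: %s\n",
    x$subject_id, x$trial_id,
    ifelse(is.na(x$condition_label), "?", x$condition_label),
    length(x$time), x$sampling_rate, diff(range(x$time)),
    paste(names(x$markers), collapse = ", ")
  ))
  if (!is.null(x$turn_window)) {
    cat(sprintf(
      "  turn window: %.2f-%.2f s\n", x$turn_window[1], x$turn_window[2]
    ))
  }
  invisible(x)
}

# marker column names in the wide CSV schema: <marker>_<coord>
marker_columns <- function(marker_names) {
  as.vector(t(outer(marker_names, c("x", "y", "z"), paste, sep = "_")))
}

#' Write a marker trial to CSV
#'
#' The wide schema has one row per frame: a `time_s` column followed by
#' `<marker>_x`, `<marker>_y`, `<marker>_z` columns in cm. Metadata is
#' stored in `# key: value` comment lines at the top of the file, so a trial
#' round-trips through [read_trial_csv()] without a sidecar file.
#'
#' @param trial a [gait_trial()].
#' @param path output file path.
#' @param digits significant digits written (default preserves doubles
#'   exactly enough for a lossless round-trip in practice).
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path, digits = 10) {
  gm_assert(inherits(trial, "gait_trial"), "'trial' must be a gait_trial")
  gm_assert(length(trial$time) > 0L, "no samples", "gaitmark_schema_error")
  con <- tryCatch(
    file(path, "w"),
    error = function(e) {
      gm_stop(
        sprintf("cannot open '%s' for writing", path), "gaitmark_io_error"
      )
    }
  )
  on.exit(close(con))
  meta <- c(
    "# gaitmark trial v1",
    sprintf("# sampling_rate_hz: %.10g", trial$sampling_rate),
    "# units: cm",
    sprintf("# condition: %s", trial$condition_label),
    sprintf("# trial_id: %s", trial$trial_id),
    sprintf("# subject_id: %s", trial$subject_id)
  )
  if (!is.null(trial$turn_window)) {
    meta <- c(meta, sprintf(
      "# turn_window_s: %.10g %.10g",
      trial$turn_window[1], trial$turn_window[2]
    ))
  }
  writeLines(meta, con)
  dat <- data.frame(time_s = trial$time)
  for (m in names(trial$markers)) {
    for (cc in c("x", "y", "z")) {
      dat[[paste(m, cc, sep = "_")]] <- trial$markers[[m]][, cc]
    }
  }
  num <- vapply(dat, is.numeric, logical(1))
  dat[num] <- lapply(dat[num], signif, digits = digits)
  utils::write.table(
    dat,
    con,
    sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

parse_trial_meta <- function(path) {
  head_lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  out <- list()
  for (ln in grep(":", meta_lines, value = TRUE)) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    out[[key]] <- val
  }
  out
}

#' Read a marker trial from CSV
#'
#' Reads the wide schema written by [write_trial_csv()]. Files that declare
#' `units: mm` are converted to cm on read. Timestamps must be uniform
#' within 1% of the sample period.
#'
#' @param path path to a trial CSV file.
#' @return A [gait_trial()].
#' @export
read_trial_csv <- function(path) {
  gm_assert(
    file.exists(path), sprintf("trial file '%s' does not exist", path),
    "gaitmark_io_error"
  )
  meta <- parse_trial_meta(path)
  dat <- utils::read.csv(path, comment.char = "#")
  gm_assert(
    "time_s" %in% names(dat), "column 'time_s' is required",
    "gaitmark_schema_error"
  )
  gm_assert(nrow(dat) > 0L, "no samples", "gaitmark_schema_error")

  for (m in required_markers()) {
    miss <- setdiff(paste(m, c("x", "y", "z"), sep = "_"), names(dat))
    if (length(miss) > 0L) {
      gm_stop(
        sprintf(
          "required marker '%s' incomplete: missing column(s) %s",
          m, paste(miss, collapse = ", ")
        ),
        "gaitmark_schema_error"
      )
    }
  }
  marker_names <- unique(sub("_[xyz]$", "", setdiff(names(dat), "time_s")))

  time <- dat$time_s
  if (length(time) > 2L) {
    period <- stats::median(diff(time))
    dev <- max(abs(diff(time) - period))
    gm_assert(
      dev <= 0.01 * period,
      sprintf(
        "non-uniform timestamps: max deviation %.3g s exceeds 1%% of the %.3g s sample period",
        dev, period
      ),
      "gaitmark_timing_error"
    )
  }
  fs <- if (!is.null(meta$sampling_rate_hz)) {
    as.numeric(meta$sampling_rate_hz)
  } else {
    1 / stats::median(diff(time))
  }

  scale <- 1
  if (!is.null(meta$units)) {
    gm_assert(
      meta$units %in% c("cm", "mm"),
      sprintf("unsupported units '%s' (use cm or mm)", meta$units),
      "gaitmark_schema_error"
    )
    if (meta$units == "mm") scale <- 0.1
  }
  markers <- lapply(stats::setNames(marker_names, marker_names), function(m) {
    out <- as.matrix(
      dat[, paste(m, c("x", "y", "z"), sep = "_"), drop = FALSE]
    ) * scale
    colnames(out) <- c("x", "y", "z")
    out
  })

  turn_window <- if (!is.null(meta$turn_window_s)) {
    as.numeric(strsplit(meta$turn_window_s, "\\s+")[[1]])
  }
  gait_trial(
    time = time, markers = markers, sampling_rate = fs,
    condition_label = if (is.null(meta$condition)) NA_character_ else meta$condition,
    trial_id = if (is.null(meta$trial_id)) basename(path) else meta$trial_id,
    subject_id = if (is.null(meta$subject_id)) NA_character_ else meta$subject_id,
    turn_window = turn_window
  )
}

#' Validate a trial and repair short marker gaps
#'
#' Occlusion gaps (`NA` runs) of at most `max_gap` samples are filled by
#' linear interpolation; any longer gap, or a gap touching the start or end
#' of the recording, marks the trial excluded — incomplete trials are
#' excluded from analysis rather than extrapolated.
#'
#' @param trial a [gait_trial()].
#' @param max_gap largest interpolatable gap, in samples (default 10, i.e.
#'   0.1 s at 100 Hz).
#' @return A list of class `gait_validation` with elements `verdict`
#'   (`"keep"` or `"exclude"`), `report` (per-marker gap counts and longest
#'   gap), `duration` (s) and `trial` (the gap-filled trial when kept).
#' @export
validate_trial <- function(trial, max_gap = 10) {
  gm_assert(inherits(trial, "gait_trial"), "'trial' must be a gait_trial")
  rows <- list()
  exclude <- FALSE
  markers <- trial$markers
  for (m in names(markers)) {
    mat <- markers[[m]]
    n_gap <- 0L
    longest <- 0L
    edge_gap <- FALSE
    for (cc in c("x", "y", "z")) {
      v <- mat[, cc]
      na <- is.na(v)
      if (any(na)) {
        r <- rle(na)
        runs <- r$lengths[r$values]
        n_gap <- n_gap + length(runs)
        longest <- max(longest, runs)
        if (na[1] || na[length(na)]) edge_gap <- TRUE
        if (max(runs) <= max_gap && !na[1] && !na[length(na)]) {
          idx <- seq_along(v)
          v <- stats::approx(idx[!na], v[!na], xout = idx)$y
          mat[, cc] <- v
        }
      }
    }
    markers[[m]] <- mat
    bad <- longest > max_gap || edge_gap
    if (bad) exclude <- TRUE
    rows[[m]] <- data.frame(
      marker = m, n_gaps = n_gap, longest_gap = longest,
      edge_gap = edge_gap, interpolated = n_gap > 0L && !bad
    )
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  trial$markers <- markers
  structure(
    list(
      verdict = if (exclude) "exclude" else "keep",
      report = report,
      duration = diff(range(trial$time)),
      trial = if (exclude) NULL else trial
    ),
    class = "gait_validation"
  )
}

#' @export
print.gait_validation <- function(x, ...) {
  cat(sprintf(
    "<gait_validation> verdict: %s (%.1f s)\n", x$verdict, x$duration
  ))
  print(x$report)
  invisible(x)
}
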