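#' Smoothing configuration
#'
#' The default smoother convolves the signal with a unit-sum Hanning window
#' of 40 samples (0.4 s at 100 Hz), chosen so the window stays shorter than
#' half a typical gait cycle; normalizing the kernel to unit sum preserves
#' signal amplitude at DC, the property that motivates convolution smoothing
#' over sharper low-pass filters for extrema-based gait event detection. A
#' Savitzky-Golay filter is available as an alternative.
#'
#' The window can be given in samples (`window_samples`) or seconds
#' (`window_s`, converted at the trial's sampling rate); the seconds form is
#' the portable default for non-100 Hz data. Windows of 0.5 s or longer are
#' rejected: they would span more than half a gait cycle and can merge
#' adjacent extrema.
#'
#' @param method `"hanning_convolution"` (default) or `"savitzky_golay"`.
#' @param window_samples window length in samples; overrides `window_s`.
#' @param window_s window length in seconds (default 0.4).
#' @param sg_polyorder polynomial order for the Savitzky-Golay filter
#'   (default 3; the filter length must exceed the order, and is forced odd).
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(method = c("hanning_convolution", "savitzky_golay"),
                             window_samples = NULL,
                             window_s = 0.4,
                             sg_polyorder = 3) {
  method <- match.arg(method)
  if (!is.null(window_samples)) {
    gm_assert(
      is.numeric(window_samples) && length(window_samples) == 1L &&
        window_samples >= 3,
      "'window_samples' must be a single count >= 3"
    )
  } else {
    gm_assert(
      is.numeric(window_s) && length(window_s) == 1L && window_s > 0,
      "'window_s' must be a single positive duration"
    )
  }
  structure(
    list(
      method = method,
      window_samples = if (is.null(window_samples)) NULL else as.integer(window_samples),
      window_s = window_s,
      sg_polyorder = as.integer(sg_polyorder)
    ),
    class = "smoothing_config"
  )
}

resolve_window <- function(config, fs, n) {
  win <- if (!is.null(config$window_samples)) {
    config$window_samples
  } else {
    as.integer(round(config$window_s * fs))
  }
  gm_assert(
    win >= 3L,
    sprintf("smoothing window of %d samples is too short (minimum 3)", win)
  )
  gm_assert(
    win / fs < 0.5,
    sprintf(
      "smoothing window of %d samples is %.2f s at %g Hz; it must stay below 0.5 s (half a gait cycle)",
      win, win / fs, fs
    )
  )
  if (n <= win) {
    gm_stop(
      sprintf(
        "signal of %d samples is shorter than the %d-sample smoothing window",
        n, win
      ),
      "gaitmark_length_error"
    )
  }
  win
}

# Hanning taps without the zero endpoints, normalized to unit sum.
hanning_kernel <- function(n) {
  k <- 1 - cos(2 * pi * seq_len(n) / (n + 1))
  k / sum(k)
}

reflect_pad <- function(x, n_pad) {
  n <- length(x)
  c(rev(x[2:(n_pad + 1)]), x, rev(x[(n - n_pad):(n - 1)]))
}

#' Smooth a marker signal
#'
#' Convolves `x` with the configured kernel. Output length equals input
#' length; edges are handled by reflection padding, which avoids the
#' spurious boundary extrema that zero padding would create.
#'
#' @param x numeric signal (cm).
#' @param fs sampling rate in Hz.
#' @param config a [smoothing_config()].
#' @return Smoothed numeric vector, `length(x)`.
#' @export
#' @examples
#' smooth_signal(sin(seq(0, 10, 0.01)) + rnorm(1001, 0, 0.05), fs = 100)
smooth_signal <- function(x, fs, config = smoothing_config()) {
  gm_assert(inherits(config, "smoothing_config"), "'config' must be a smoothing_config")
  gm_assert(is.numeric(x), "'x' must be numeric")
  win <- resolve_window(config, fs, length(x))
  if (config$method == "savitzky_golay") {
    if (win %% 2L == 0L) win <- win + 1L
    gm_assert(
      config$sg_polyorder < win,
      "'sg_polyorder' must be smaller than the filter length"
    )
    return(as.numeric(signal::sgolayfilt(x, p = config$sg_polyorder, n = win)))
  }
  kern <- hanning_kernel(win)
  padded <- reflect_pad(x, win)
  sm <- stats::filter(padded, kern, method = "convolution", sides = 1)
  # sides = 1 delays the output by the kernel length; re-center on the input
  # grid (an even window keeps an inherent half-sample offset, constant for
  # every extremum and removed by raw-signal event refinement downstream)
  offset <- win + (win + 1L) %/% 2L
  as.numeric(sm[seq_along(x) + offset - 1L])
}
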