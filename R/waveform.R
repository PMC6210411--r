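# Periodic marker waveforms for the synthetic generator.
#
# One gait cycle of a vertical marker signal is modelled as a C1 piecewise
# raised-cosine curve with a valley (ground contact) at phase 0, a single
# peak at phase `rise`, and the next valley at phase `period`. Each extremum
# sits inside a locally *symmetric* cosine cap of half-width
# `cap_frac * min(rise, fall)`; symmetric caps keep the extremum locations
# unbiased under symmetric smoothing kernels and local parabolic fits, which
# is what makes sample-accurate event recovery possible downstream.
#
# `shoulder_frac` sets the cap amplitude (depth below the peak / height above
# the valley) as a fraction of the full excursion; the segments between caps
# are monotone raised-cosine steps, so exactly one peak and one valley exist
# per cycle.

cycle_wave <- function(phi, period, rise, amp,
                       cap_frac = 0.4, shoulder_frac = 0.2) {
  fall <- period - rise
  w <- cap_frac * min(rise, fall)
  hv <- shoulder_frac * amp
  dp <- shoulder_frac * amp
  p <- phi %% period
  z <- numeric(length(p))

  i <- p <= w
  z[i] <- hv * (1 - cos(pi * p[i] / w)) / 2
  i <- p > w & p <= rise - w
  u <- (p[i] - w) / (rise - 2 * w)
  z[i] <- hv + (amp - dp - hv) * (1 - cos(pi * u)) / 2
  i <- p > rise - w & p <= rise + w
  z[i] <- amp - dp * (1 - cos(pi * (p[i] - rise) / w)) / 2
  i <- p > rise + w & p <= period - w
  u <- (p[i] - rise - w) / (fall - 2 * w)
  z[i] <- hv + (amp - dp - hv) * (1 + cos(pi * u)) / 2
  i <- p > period - w
  z[i] <- hv * (1 - cos(pi * (period - p[i]) / w)) / 2
  z
}

# Cumulative forward progression of the heel in cm. The heel is stationary
# through stance and the early part of swing, then advances by `step_length`
# along a raised-cosine ramp confined to the swing interior
# [rise + 0.30*fall, rise + 0.85*fall], so the position is flat around both
# the peak (swing onset) and the following valley (heel strike). Step length
# read at consecutive peaks is then exact by construction and robust to
# small event-timing error.
progression_wave <- function(phi, period, rise, step_length) {
  fall <- period - rise
  t_a <- rise + 0.30 * fall
  t_b <- rise + 0.85 * fall
  cyc <- floor(phi / period)
  p <- phi - cyc * period
  ramp <- ifelse(
    p <= t_a, 0,
    ifelse(p >= t_b, 1, (1 - cos(pi * (p - t_a) / (t_b - t_a))) / 2)
  )
  (cyc + ramp) * step_length
}

# Smoothly rotate the walking heading by 90 degrees across the turn window.
heading_angle <- function(t, turn_start, turn_duration) {
  if (is.null(turn_start)) {
    return(rep(0, length(t)))
  }
  u <- (t - turn_start) / turn_duration
  u <- pmin(pmax(u, 0), 1)
  (pi / 2) * (1 - cos(pi * u)) / 2
}

# Turn a scalar progression distance into a planar path that follows the
# (possibly rotating) heading, plus a lateral offset perpendicular to it.
path_from_progression <- function(s, psi, lateral_offset) {
  ds <- diff(c(s[1], s))
  x <- cumsum(ds * cos(psi))
  y <- cumsum(ds * sin(psi))
  x <- x + lateral_offset * (-sin(psi))
  y <- y + lateral_offset * cos(psi)
  list(x = x, y = y)
}
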