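---
title: "Methods: marker-based spatiotemporal gait analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based spatiotemporal gait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmark)
```

## The gait model

gaitmark analyzes walking trials recorded with an optical motion-capture
system at a fixed sampling rate (nominally 100 Hz) through reflective
markers on the heels and toes. The analysis rests on a deliberately simple
event model of the vertical (z) heel trajectory: within every gait cycle
the heel height traces exactly one valley — the heel strike, when the heel
meets the ground — and one peak, reached as the heel rises toward the end
of stance and through swing. Writing $t_{V(k)}$ and $t_{P(k)}$ for the
times of the $k$-th valley and peak, and $t_{Vto}$ for the nearest valley
of the vertical *toe* trajectory (the foot-flat instant), the per-cycle
parameters are

$$
\begin{aligned}
\mathrm{GCT}(k) &= t_{V(k)} - t_{V(k-1)} &\qquad
\mathrm{SW}(k) &= t_{V(k)} - t_{P(k)} \\
\mathrm{ST}(k) &= \mathrm{GCT}(k) - \mathrm{SW}(k) &\qquad
\mathrm{IDS}(k) &= t_{Vto} - t_{V(k-1)} \\
\mathrm{TDS}(k) &= t_{P(k)} - t_{Vto} &\qquad
\mathrm{SH}(k) &= z_{P(k)} - z_{V(k-1)} \\
\mathrm{SL}(k) &= x_{P(k)} - x_{P(k-1)} &\qquad
\mathrm{Vel}(k) &= \mathrm{SL}(k)/\mathrm{GCT}(k)
\end{aligned}
$$

where time-like symbols are event *times*, SH reads the event *heights*,
and SL reads the forward (x) heel coordinate at consecutive peaks. Three
consequences of these definitions are worth making explicit, because they
shape everything downstream:

* **GCT = SW + ST holds exactly**, by construction; it is asserted as an
  identity, never within a tolerance.
* **IDS + TDS = ST per foot** whenever the toe valley exists, because the
  three quantities triangulate the same two events. Published summary
  tables built from the same formulas do not always satisfy this (the
  package's bundled reference table has one such inconsistent cell, which
  the consistency routine reports but the test suite deliberately does not
  assert); the per-foot formulas are implemented as defined, not
  "corrected" toward a bilateral definition of double support.
* **The first cycle of a trial has no SL or velocity** — it has no
  preceding peak. It still contributes to the temporal parameters.

The toe valley assigned to cycle $k$ is searched strictly inside
$(t_{V(k-1)}, t_{P(k)}]$, which makes IDS and TDS nonnegative by
construction; a toe valley exactly at the heel valley yields IDS = 0, the
running limit where initial double support vanishes. Cycles for which the
search fails are flagged and get missing IDS/TDS; negative durations from
event mis-ordering flag the cycle invalid rather than being clamped.

## Smoothing

Extrema detection on raw marker data is unstable, so the vertical signals
are smoothed first. The default is convolution with a **40-sample Hanning
window normalized to unit sum** (0.4 s at 100 Hz, below half of a typical
gait cycle). The unit-sum normalization matters: the argument for plain
convolution smoothing over sharper low-pass filters in this setting is
that it does not shrink the signal's amplitude at DC, and an unnormalized
Hanning kernel would rescale the whole trace. Window length can be given
in seconds (`window_s = 0.4`, the portable spelling) or samples; windows
of 0.5 s or more are rejected because they approach the half-cycle scale
and can merge adjacent extrema. A Savitzky–Golay filter
(`method = "savitzky_golay"`, default length 41, order 3) is retained as
an alternative for comparison.

Edges are handled by reflection padding — the choice is not forced by
anything, but reflection avoids the spurious boundary extrema that zero
padding creates. An even-length window carries an inherent half-sample
alignment offset; it is constant across all events and removed by the
refinement step below.

## Event detection, alternation, and refinement

Candidate events are all local maxima and minima of the smoothed heel-z
signal over a ±10-sample neighborhood with topographic prominence of at
least 2 cm (`extraction_config()`). The prominence floor sits far below
the smallest plausible step height (reference summaries put the smallest
group mean near 14.5 cm) and far above smoothed marker noise; plateau
extrema resolve to their first sample; ties between equal-height
candidates keep the earlier event, so output is deterministic.

Candidates then pass through the **alternation rule**: between two
consecutive valleys only the highest peak survives, between two
consecutive peaks only the lowest valley, repeated until the series
strictly alternates with every peak above its neighboring valleys, then
trimmed to start and end with a valley so only complete cycles remain.
This is the mechanism that discards turning-phase detection artifacts.
The rule is idempotent, and the property-based tests drive it with
randomized candidate sets.

Two further stages are design choices of this package:

* **Raw-signal refinement.** A symmetric smoothing kernel spanning 0.4 s
  systematically lags the extrema of asymmetric waveforms (stance is
  roughly three times longer than swing, so heel-z rises slowly and falls
  fast) and attenuates peak heights — for short swing phases by a
  substantial fraction. Event times and heights are therefore
  re-estimated on the *unsmoothed* signal: each candidate is re-centered
  on the raw extremum nearby, then a least-squares parabola over ±4
  samples is iterated twice, yielding sub-sample times and
  amplitude-true heights. Fits that curve the wrong way (possible in
  heavy noise) fall back to the sample-level estimate. The ±4-sample
  window is a bias/variance compromise: wider windows leak the quartic
  term of curved extremum neighborhoods into the apex estimate, narrower
  windows amplify noise.
* **Explicit turn windows.** Turning-phase cycles must be excluded from
  straight-walking analysis, but heel-z keeps cycling through a turn, so
  the turn cannot be inferred from the extrema themselves. The package
  requires an explicit turn window in the trial metadata and drops every
  cycle whose span overlaps it — whole cycles only, never truncated
  ones. How the turn was delimited is the one stage where a source of
  information outside the marker model is required.

Step length reads the forward heel coordinate at the two peak times as a
±3-sample local mean, so single-sample coordinate noise does not pass
straight into SL.

## Condition summaries, asymmetry, statistics

Condition summaries report the mean and sample SD of each parameter over
cycles, pooled across trials and subjects within a condition. The
support-phase ratios are ratios of *means* — ST/GCT, IDS/GCT, TDS/GCT,
IDS/ST, TDS/ST, in percent — and the condition velocity is the mean of
per-cycle velocities, not mean SL over mean GCT; this is the convention
under which summary tables are internally consistent
(IDS/ST = (IDS/GCT)/(ST/GCT) to rounding). `derived_support_ratios()` and
`stance_identity_residuals()` check exactly these identities on any table
in the summary layout, including the bundled published reference tables.

Bilateral symmetry is quantified by the asymmetry index
$I_a = (X_L - X_R)/\max(X_L, X_R) \times 100$ applied to per-side
condition means of GCT, SH, SL and velocity. The index is reported in
percent with range $[-100, 100]$ (the percent scale is what the defining
formula produces); it is zero under perfect symmetry, positive when the
left side's value is larger, antisymmetric under side exchange and
scale-invariant. Per-cycle left/right pairing is undefined for
independently cycling feet and is not attempted; indices pool cycles
within a condition, and per-subject summaries can be obtained by
filtering the cycle table before summarizing.

Condition comparisons follow the two-stage recipe: a Shapiro–Wilk screen
of each group (flagging departures from normality at p ≤ 0.05 — flagged,
not auto-switched to a nonparametric test) followed by a two-sided
two-sample t-test at α = 0.05 on per-cycle values. **Welch's
unequal-variance form is the default**: the pooled test is available via
`var_equal = TRUE` for strict reproduction of analyses that assumed equal
variances, but Welch is the safer default when cycle counts and
dispersions differ between conditions. Comparisons are unpaired — cycles,
not subjects, are the units — and no multiple-testing correction is
applied, matching the reporting style the package mirrors; both choices
are visible in the output so a stricter analysis can be layered on top.
The per-trial report (mean and variance of GCT per trial and side, in
cue-speed order) supports adaptation analyses across consecutive trials.

## The synthetic gait generator

Real recordings behind the published group tables are not available, so
validation rests on a generator (`generate_trial()`) that emulates the
statistical structure the analysis assumes, with known ground truth.

Per side, heel-z follows a C1 piecewise raised-cosine wave: one valley
(heel strike) and one peak per cycle, rising over stance and falling over
swing, with amplitude equal to the configured step height. Each extremum
sits inside a **locally symmetric cosine cap** (half-width 40% of the
shorter adjacent phase). The caps are the generator's key numerical
design decision: a waveform that is flat through stance would turn every
heel strike into a plateau whose smoothed location shifts by half the
kernel width, making sample-accurate event recovery impossible for *any*
detector operating on the smoothed trace — not because gait is
ambiguous, but as a pure artifact of the test signal. Locally symmetric
extrema keep both the smoothed locations and the parabolic refinements
unbiased, so detection accuracy measures the pipeline, not the fixture.
Toe-z is a smaller wave (6 cm default excursion — any positive value
with a unique valley per cycle serves the formulas) whose valley falls
`ids_fraction × GCT` after the same side's heel strike. The forward heel
coordinate advances by the configured step length along a smooth ramp
confined to the swing interior, flat around both peak and valley so SL
is exact by construction. Left and right are phase-offset by half a
cycle, the standard bipedal alternation. Noise is additive i.i.d.
Gaussian on every coordinate. An optional turning segment rotates the
walking heading by 90° across a window while vertical cycling continues,
exercising the exclusion logic.

Because the per-foot formulas force TDS = ST − IDS, the scenario's
`tds_fraction` cannot independently position any event; it enters only
the feasibility invariant `swing + ids + tds < 1` (stance must contain
both double supports plus single support). Ground truth records all
event times, and `ground_truth_parameters()` applies the event-time
definitions to them — the oracle is the same arithmetic on exact times,
independent of the detection path.

Default scenario values correspond to unassisted parkinsonian walking in
the bundled reference summaries: GCT 1.29 s, swing fraction 0.27
(0.35/1.29), IDS fraction 0.1875, step height 21.2 cm, step length
93 cm, at 100 Hz with 0.2 cm marker noise — a plausible optical-capture
noise level; the generator does not model the heavier-tailed artifacts
(marker swaps, soft-tissue wobble) of real captures.

What passing synthetic tests does and does not show: they establish that
the smoothing/detection/extraction chain recovers the event structure it
is designed for — sample-accurate at zero noise, within a few sample
periods under realistic noise, across cycle times of 0.9–2.0 s and step
heights of 10–25 cm — and that asymmetry injected at generation is
recovered end-to-end. They do not certify performance on pathological
waveforms outside the one-peak-per-cycle model (severe shuffling,
festination, freezing episodes), on marker dropout beyond the linear
interpolation policy, or on turns that are not annotated.

## Validation problem sizes and numerical choices

The validation suite uses 50 seeded scenarios (10 noiseless, 40 with
noise drawn from 0.05–0.3 cm) of 8 cycles per side for the recovery
sweep, single trials of 12 cycles per side for the asymmetry checks, and
1000 replicates of n = 30 per group for the type-I calibration of the
comparison module — sizes chosen so the whole suite runs in seconds
while estimating rates with adequate precision. Other numerical
conventions collected in one place: ties in event selection keep the
earlier event; plateau extrema resolve to their first sample; extrema
whose neighborhood window is truncated by the signal edge are not
certified; marker gaps up to 10 samples are linearly interpolated and
anything longer (or touching a recording edge) excludes the trial;
trials whose timestamps deviate from uniformity by more than 1% of the
sample period are rejected; coordinates declared in mm are converted to
cm on read.

## Known limitations

* The event model measures a stride-like step height and length
  (peak-to-peak of one foot) and a swing defined from the heel-z peak,
  which starts somewhat before anatomical toe-off; parameters are
  faithful to their defining formulas rather than to instrumented
  gold-standard phase boundaries (force plates, footswitches).
* IDS derives from the same foot's toe valley, so the double-support
  split is a per-foot surrogate of a bilateral quantity.
* Turn exclusion requires annotated turn windows.
* CSV (wide schema, one row per frame) is the only tested input format;
  binary motion-capture containers would need an external converter.
* Asymmetry indices pool cycles across subjects within a condition;
  subject-stratified analyses must filter the cycle table first.
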