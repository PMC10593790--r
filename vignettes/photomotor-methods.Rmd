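---
title: "Models and methods behind photomotor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photomotor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(photomotor)
```

photomotor processes three streams recorded during rodent behavior:
dual-channel fiber photometry, body-part tracking tables, and per-sweep
spike trains around optogenetic stimulation. This vignette documents the
models each stage assumes, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the problem was genuinely
open.

## Photometry model

The 465 nm channel reports calcium-dependent fluorescence; the 405 nm
channel is excited near the indicator's isosbestic point and carries the
same bleaching and motion artifacts but (ideally) no activity signal. The
pipeline assumes the control maps onto the signal affinely, fits
`F0 = a * F405 + b` by ordinary least squares, and takes
`dFF = 100 * (F465 - F0) / F0`. The fit is per-session by default; for
rotarod sessions it is restricted to the rest epochs flanking the run so
running-related activity cannot leak into the baseline. A `degenerate_fit`
error is raised when the control channel is constant, and `compute_dff`
refuses non-positive `F0` rather than emitting infinities.

Normalization uses the modified z-score
`z = 0.6745 * (x - median(x)) / MAD(x)` with the raw (unscaled) median
absolute deviation; the 0.6745 factor makes `z` agree with a standard
z-score under normality while staying insensitive to transient-rich tails.
The median of the output is exactly zero by construction.

Key parameters (all arguments, defaults in parentheses):

* decimation factor (10) -- block means, so decimation also anti-aliases;
  1017.3 Hz acquisition becomes 101.73 Hz;
* initial trim (180 s) -- discards the settling/fast-bleaching head; the
  acceptable range in practice is 3-5 min, so the value is exposed;
* moving-percentile baseline: 8th percentile in a centered window (30 s).
  The window width is a free parameter because no canonical value exists;
  30 s is several times the transient decay yet much shorter than bleaching.
  In rest-anchored mode the percentile is computed on rest spans only and
  interpolated across the run, so the run epoch is not deformed;
* transient pre-smoothing: 0.5 s centered boxcar;
* peak detection: minimum prominence 0.5 z relative to the preceding local
  minimum and 0.2 s minimum separation (the smaller of two close peaks is
  dropped). The prominence/separation pair is not prescribed anywhere, so
  both are exposed with these defaults.

All moving windows shrink at the series edges instead of padding:
reflection or zero padding would invent data at trial boundaries exactly
where event-aligned analyses read values.

## Kinematics

Tracking tables arrive in image pixels with y increasing downward.
`calibrate_and_upsample()` converts once to y-up centimeters using a known
physical span (42 cm open-field corner distance, 3 cm rotarod height) and
linearly resamples to 100 Hz to share the calcium grid; all downstream
math assumes y-up, which fixes the sign convention of rotations
(counter-clockwise positive) and the meaning of "jump up". Points with
likelihood below 0.9 are replaced by natural-spline interpolation over
valid frames (nearest-valid at the edges); the exact inpainting kernel of
upstream tools is unspecified, and a cubic spline with linear fallback
reproduces their behavior on smooth trajectories to well under a pixel.
Likelihoods are never altered, so gates stay auditable.

Bout segmentation works on the 2 s-smoothed body-center speed: candidate
epochs exceed 5 cm/s, epochs whose connecting trough never falls below
3 cm/s are merged, the onset is the last local minimum before the upward
3 cm/s crossing and the offset the last local maximum before the downward
5 cm/s crossing. The look-back for either extremum is bounded to 2 s --
without a bound, a long plateau would let the search capture extrema that
belong to the previous bout. A session already above threshold at frame 1
opens a censored bout at frame 1. Whether bout detection should run at the
native video rate or the 100 Hz grid is not prescribed; both work, and the
recovery tests run at native rate where a one-frame tolerance is
meaningful.

Jump detection robust-z-scores the lower-body Y position and takes local
minima as jump onsets and maxima as offsets, under a three-part session
gate: frames below 0.95 likelihood are excluded, low-likelihood epochs of
at least 1 s are excluded, and sessions with under 50% valid frames raise
a `session_excluded` condition rather than returning half-trustworthy
events.

Motor-state frames are labeled locomotion (body speed > 4.5 cm/s),
motionless (every part <= 0.8 cm/s) or other movement; the three labels
are exhaustive and mutually exclusive so per-epoch fractions sum to one.
The arena periphery is the outermost 10 cm band, measured from an explicit
arena origin -- anchoring on observed position minima would shift the zone
boundary whenever the animal avoids the walls.

## Event-aligned statistics and the surrogate test

`align_to_events()` windows a trace around events, drops events whose
window leaves the recording, and optionally subtracts each trial's mean
over a stated baseline window -- (-5, -1) s before jumps, (-15, -5) s
before opto trials -- making the baseline mean exactly zero per row.

`lagged_pearson()` scans integer-sample lags over +/-5 s by default and
computes r on the shift-trimmed overlap, never on zero-padded series
(padding biases r toward zero). The reported "best" maximizes `|r|` but
returns the signed value and its lag: maximizing the signed value instead
would silently discard anticorrelated coupling.

`phase_shuffle()` builds surrogates that preserve the Fourier amplitude
spectrum (hence mean, total power and autocorrelation) while randomizing
all non-DC, non-Nyquist phases with conjugate symmetry. This nulls exactly
the property under test -- phase-locked covariation -- while keeping each
series' spectral content, so the surrogate distribution of best-`|r|`
embodies "same signals, no temporal relation".
`shuffle_correlation_test()` compares per-subject real best-`|r|` against
a surrogate population by a two-sided rank-sum test. In the default pooled
mode one surrogate population is built by visiting subjects round-robin;
a per-subject mode (n surrogates per subject) is available where a
subject-level null is wanted. The pooled mode mirrors how such tests are
usually reported (one cloud of shuffled values against the real points).
Type-I calibration is checked empirically in the acceptance suite:
with independent broadband inputs the rejection rate at alpha = 0.05 over
500 replicates falls inside (0.03, 0.08).

## Ephys classification

PSTHs use 1 ms half-open bins `[t, t+1)` from -1000 to +2000 ms, summed
over sweeps and expressed in Hz; spikes on bin edges go to the lower bin,
and stimulation-window means use only bins fully inside the window (the
0 ms no-light condition is analyzed over a matched 1000 ms window). Units
with a silent baseline are excluded from classification as `unanalyzable`
and counted separately -- no finite criterion applies to them.

Two criteria are implemented. The one-third criterion labels a unit
inhibited when the stimulation-window mean falls to at most 2/3 of
baseline and excited at 4/3 or more. The z-score criterion is
`z = (mean_stim - mean_base) / SD_base` with cutoffs at +/-2. The baseline
SD defaults to the SD of per-sweep baseline rates (`sd_mode = "sweeps"`),
i.e. trial-to-trial variability of the 1 s pre-stimulus rate. The
alternative -- SD across the 1000 one-ms bins of the summed PSTH
(`sd_mode = "bins"`) -- is provided for audit but cannot serve as the
operating criterion: at 1 ms resolution a Poisson baseline at 30 Hz has a
bin SD near 55 Hz against a 30 Hz mean, so even complete silencing only
reaches z of about -0.55 and the +/-2 cutoff would never fire. Only the
per-sweep mode makes the two criteria agree on extreme units, which is the
behavior the cutoffs presuppose.

Population tables count inhibited versus non-inhibited units per region
and stimulation duration and compare drug groups with Fisher's exact test
(`stats::fisher.test`, cross-checked in the tests against a hypergeometric
enumeration oracle).

## Closed-loop trigger replay

The online dFF estimate is
`[(F - Fo)/Fo]_465 - [(F - Fo)/Fo]_405`, with each `Fo` a trailing mean
over the past 120 s, followed by a causal first-order recursive low-pass
at 1 Hz (the online filter family is not prescribed; a first-order
recursion is the natural causal choice and is validated against a direct
recurrence oracle). Nothing at output time t uses samples after t, which a
mutation test asserts directly.

The calcium-peak rule fires when the online signal has been above
threshold for 250 ms and a local peak has occurred within the run (the
conjunction; either sub-rule can be disabled). The logged trigger time
adds a fixed 0.2 s latency modeling the mean online compute delay; jitter
is deliberately not simulated by default. The speed rule requires 5 s
(or 2 s for slow-opsin assays) of rest below 3 cm/s, then a rise of the
1 s trailing-averaged speed above 8 cm/s, then 5 s without falling below
the floor; the averaging span for "average speed" is not prescribed and
1 s is exposed as a parameter. Triggers honor a refractory interval, and
every returned log re-validates that constraint at construction.

## The synthetic-data generator

One `sim_config()` drives all generators from a single integer seed;
per-component sub-streams are derived deterministically, so identical
configs are bit-identical across runs. The photometry generator draws
transient times from a Poisson process whose rate is
`transient_rate * (1 + coupling_gain * speed / 5)` (5 cm/s is the
bout-entry scale), convolves them with a difference-of-exponentials kernel
(rise 0.07 s, decay 0.8 s -- slow-indicator kinetics; no canonical kernel
exists, and a two-exponential is the standard minimal model), scales them
by log-normal amplitudes (mean 3 a.u., CV 0.3; the amplitude distribution
is a parameter because none is established), and adds a shared exponential
bleach (tau 600 s), an optional motion artifact injected at full gain into
the 465 and at 0.8x into the 405, and white noise. Tracking follows a
smooth heading random walk whose speed is a trapezoid per scheduled bout
(1 s ramps) over a 0.5 cm/s resting baseline inside a 42 cm arena; eight
body parts ride rigidly on the body frame; the rotarod variant oscillates
the lower body between 0 and 3 cm as a triangular wave starting mid-rise
so every extremum is interior. Spike trains are homogeneous Poisson at
30 Hz with the in-stimulus rate multiplied by `1 - inhibition_depth`
(inhibited), `excited_gain` (excited) or 1 (none).

What the generator does **not** emulate -- and therefore what passing
tests do not certify on real data: hemodynamic or pH artifacts that differ
between 465 and 405 beyond a scale factor, indicator nonlinearity and
saturation, non-exponential bleaching, tracking identity swaps or
out-of-frame occlusions, bursting or adapting spike statistics, and any
biomechanics beyond the trapezoid/triangle kinematics. Ground-truth bout
landmarks are the trapezoid's rise foot and plateau end, which is exactly
what the onset/offset rules estimate on the noiseless profile; recovery
tests are therefore sharp (one-frame tolerance) but speak to the detector
logic, not to pose-estimation noise.

## Numerical choices and degenerate inputs

* Moving windows truncate at boundaries; no padding anywhere.
* The running percentile is evaluated on a stride (window/10) and linearly
  interpolated -- exact for the global-window case, and bounded error
  elsewhere since the 8th percentile of a slow baseline varies slowly.
* Peak separation ties resolve in favor of the larger peak.
* `MAD = 0`, constant control channels, zero-variance correlation
  overlaps, silent ephys baselines and coincident snout/lower-body frames
  all raise classed conditions (`degenerate_scale`, `degenerate_fit`,
  `undefined_correlation`, `unanalyzable`, logged-skip) rather than
  propagating NaN.
* Problem sizes in the test and acceptance runs (600 s sessions at 20 Hz
  for Monte-Carlo coupling checks, 400-sample series for the 500-replicate
  surrogate calibration, 200 simulated units for classification recovery)
  were chosen so each check exercises the asymptotics it cites while the
  whole suite stays desk-scale.

## Known limitations

The isosbestic fit is affine and per-session; slow artifact
nonstationarity within a session is only partially removed. The surrogate
test's pooled mode treats surrogate draws as exchangeable across subjects;
with very heterogeneous subjects the per-subject mode is preferable. Jump
detection assumes a dominant vertical oscillation of one body part and
will under-segment gait with large horizontal excursions. The closed-loop
replay is an offline simulator of the decision rules -- it makes no
real-time guarantees and does not emulate acquisition hardware.
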