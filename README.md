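# photomotor

Analysis toolkit for experiments that record **dual-channel fiber
photometry** (a 465 nm calcium-dependent signal plus a 405 nm isosbestic
control) while a mouse behaves, together with **pose-tracking kinematics**
(DeepLabCut-dialect body-part tables) and **optogenetic in vivo
electrophysiology** (per-sweep spike times around laser stimulation). It is
aimed at basal-ganglia labs that need the standard processing chain --
dFF, robust z-scores, locomotor-bout and rotarod-jump segmentation,
event-aligned transient metrics, surrogate-tested correlations,
peri-stimulus unit classification, and offline replay of closed-loop
trigger rules -- as tested, reusable functions rather than one-off scripts.

Because raw recordings of this kind are rarely shareable, the package
ships a seeded **synthetic-data module** that generates photometry,
tracking and spike trains with known ground truth (GCaMP-like transients
kinetically coupled to locomotor speed, photobleaching, shared motion
artifacts, likelihood dropouts, stimulus-locked Poisson inhibition), so
every stage of the pipeline is testable end to end on any machine.

## The core computations

* **dFF and robust z.** The control channel is mapped onto the signal
  channel by least squares, `F0 = a * F405 + b`, and
  `dFF = 100 * (F - F0) / F0`. Traces are standardized with the modified
  z-score `z = 0.6745 * (dFF - median(dFF)) / MAD(dFF)` (raw MAD), and
  slow baseline shifts are removed by subtracting a moving 8th percentile.
* **Behavior segmentation.** Locomotor bouts open where smoothed
  body-center speed breaks 5 cm/s; the onset is the last local speed
  minimum before the upward 3 cm/s crossing and the offset the last local
  maximum before the downward 5 cm/s crossing. Rotarod jumps are local
  minima/maxima of the robust-z lower-body Y position under a 0.95
  likelihood session gate. Motor states partition frames into locomotion
  (> 4.5 cm/s), motionless (all parts <= 0.8 cm/s) and other movement.
* **Event-aligned statistics.** Trial matrices around behavioral events
  with exact baseline-window normalization; lagged Pearson correlation on
  the shift-trimmed overlap with the strongest `|r|` reported; and a
  phase-randomized surrogate test: Fourier amplitudes preserved, phases
  randomized, real vs surrogate best-`r` populations compared by
  two-sided rank-sum.
* **Unit classification.** PSTHs at 1 ms resolution over (-1000, +2000) ms
  summed across sweeps; units are inhibited/excited by the one-third
  criterion (stim mean <= 2/3 or >= 4/3 of baseline) or by
  `z = (mean_stim - mean_base) / SD_base` with cutoffs at +/-2; population
  contingency tables are compared by Fisher's exact test.
* **Closed-loop replay.** The causal online estimate
  `[(F-Fo)/Fo]_465 - [(F-Fo)/Fo]_405` (120 s trailing baselines, 1 Hz
  causal low-pass) drives a calcium-peak trigger (supra-threshold for
  250 ms plus a local peak, 200 ms latency); a speed trigger fires after
  5 s of rest followed by a mobility bout that reaches 8 cm/s and never
  drops below 3 cm/s for 5 s.

## Worked example

```r
library(photomotor)

sched <- regular_bouts(300, every_s = 60, bout_dur_s = 10, first_s = 30)
cfg <- sim_config(seed = 3, duration_s = 300, fs_photometry = 101.73,
                  bout_schedule = sched, coupling_gain = 4, noise_sd = 0.03)
sim <- simulate_photometry(cfg)
trk <- simulate_tracking(cfg)

res <- run_open_field(sim$session, trk$tracking, known_distance_px = 420,
                      factor = 1L, trim_s = 30, max_lag_s = 1)
sum(res$bouts$kind == "bout_onset")
#> [1] 5
round(c(res$lag$best_r, res$lag$best_lag_s), 3)
#> [1]  0.811 -0.737
summarize_tracing_counts(147, 159)
#> 147 / 159 = 92.5%
```

All five scheduled bouts are recovered from the tracking stream. The
strongest speed-dFF correlation is r = 0.81 at a lag of
-0.74 s: the calcium trace trails running speed by roughly the centroid
of the GCaMP-like transient kernel, as expected when speed drives
transient rates. The tracing summary reproduces a cell-count percentage
from its numerator/denominator inputs.

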