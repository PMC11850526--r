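---
title: "Event-related running-RMS analysis of mouse ECoG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-related running-RMS analysis of mouse ECoG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogrms)
```

## The experiment this package analyzes

`ecogrms` implements the analysis of a three-cohort, three-trial mouse
electrocorticography (ECoG) experiment on diagnostic-ultrasound
neuromodulation. Anesthetized mice carry four epidural electrodes (left
and right visual cortex, left and right somatosensory cortex). A session
consists of a 5-minute dark baseline, a light-titration period, a second
5-minute baseline, and three 10-minute trials separated by a 4-minute
rest after Trial 1. During each trial a 0.1-s light pulse is delivered
every 10 s — each 10-s inter-stimulus interval is an *event*, giving
about 60 events per trial. Three cohorts define the design: *US+Light*
(blinking light in all trials, transcranial diagnostic ultrasound added
during Trial 2), *Light-only* (blinking light only), and *US-only*
(ultrasound during Trial 2, never a blinking light; virtual markers keep
the segmentation comparable).

The scientific question is whether imaging-grade ultrasound changes the
magnitude of light-evoked cortical activity, measured as a wideband
running-RMS envelope, and whether the answer depends on how much of each
event one analyzes.

## The analysis chain

1. **Band-pass filter.** Each channel is filtered to 5–55 Hz with a
   zero-phase Butterworth band-pass (order 4 per pass, applied forward
   and backward). The filter is realized as a cascade of analytically
   designed second-order sections; the equivalent direct-form transfer
   function is numerically unstable at high sampling rates (at 20 kHz
   its computed poles leave the unit circle through coefficient
   rounding), while the cascade is stable at every rate the package
   supports. Zero phase matters because event scalars are means over
   time-anchored windows: any group delay would shift evoked energy
   across the `k`-second boundaries.
2. **Artifact rejection.** The recording is cut into 1-s windows; per
   channel, windows whose RMS exceeds `mean + 4 SD` of that channel's
   window-RMS distribution are excluded. The rule is
   distribution-relative, so it is invariant under amplitude rescaling
   (amplifier gain cannot change which data are kept). Rejected time is
   marked by exclusion spans, never spliced out, so event timing is
   preserved; an event overlapping any rejected span is dropped whole,
   keeping every retained scalar an average over identical support. The
   evaluation window (1 s) and the `mean + k·SD` convention are
   config-exposed (`rejection_spec()`) because the removal unit is a
   judgement call; per-channel statistics with a global union of
   rejected spans keep events aligned across channels while catching
   channel-local artifacts.
3. **Events and envelopes.** Each trial is cut into 10-s epochs at the
   stimulus markers, and a 0.25-s running-RMS envelope is computed per
   epoch. The moving window is centered with edge truncation; a trailing
   alignment is available (`running_rms(align =)`) for sensitivity
   checks, since published envelope traces can follow either convention.
4. **Subset-of-event-length scalars.** For each event and each `k` in
   1…10 s, the scalar is the mean of the envelope over the first `k`
   seconds. Short `k` isolates the evoked transient (which lasts up to
   ~4 s); `k = 10` dilutes it with ongoing activity. The per-event
   scalar — roughly 60 per mouse and 420 per 7-mouse cohort for each
   trial and `k` — is the unit of all statistics.
5. **Two-stage ratio normalization.** First, every value of a mouse is
   divided by that animal's baseline reference: the median of the
   running-RMS envelope over the last 60 s of the second baseline
   (rejected samples excluded). Second, every `(trial, k)` value is
   divided by the mouse's Trial-1 median at the same `k`, so each
   mouse's Trial-1 median becomes exactly 1 and between-trial changes
   read as ratios. Ratio normalization is used deliberately instead of
   z-scoring, which can bias event-related power comparisons; the
   across-`k` references are computed per `k` because the envelope mean
   changes systematically with window length. The Trial-1 identity is
   asserted at machine precision on every pipeline run.
6. **Statistics.** Two-sided Mann–Whitney U for pairs of cells,
   Kruskal–Wallis for three or more, on pooled per-event scalars, with
   Bonferroni families registered in `standard_families()`: profile
   comparisons per `k` (n = 10), per-cohort across-trials and trial-pair
   grids (n = 30), within-trial cohort comparisons (n = 20), the
   all-pairs intra-cohort grid (n = 90) and the inter-cohort grid
   (n = 60), giving corrected thresholds 0.005, 0.0017, 0.0025, 0.00056
   and 0.00083 at two significant figures.

One analysis channel is used by default — the left visual cortex, which
is contralateral to the stimulated right eye and under the transducer
center. The source data do not dictate this choice; it is configurable
(`analysis_config(channel =)`), and multi-channel recordings can be
analyzed channel by channel.

### Reading of "median RMS value"

The per-mouse Trial-1 reference is computed as the *median over events
of the per-event mean-envelope scalar*. The alternative reading — the
RMS of a median envelope trace — is not the default because the
per-event scalar is the declared unit of analysis; computing the
reference on the same scale as the data it normalizes keeps the
Trial-1 identity exact.

## The synthetic-data generator

All validation runs on synthetic sessions with known ground truth
(`generate_session()`, `generate_cohort()`). The generator emulates:

- **Ongoing activity:** pink (1/f-amplitude) Gaussian noise, flat below
  1 Hz, normalized to unit RMS and scaled to 50 µV — a typical
  anesthetized-mouse ECoG magnitude. Long traces are synthesized in
  power-of-two FFT blocks joined by an equal-power crossfade; this
  alters only spectral content below 1/block-duration Hz (< 0.01 Hz),
  well below both the 1 Hz flattening point and the 5 Hz analysis edge.
- **Evoked responses:** a damped-oscillation kernel (50 ms latency,
  15 Hz, 0.5 s decay, support capped at 4 s so evoked energy stays
  within the event and inside the 5–55 Hz band). Per-event amplitude is
  `300 µV × trial gain × mouse scale × event jitter`, with lognormal
  mouse scale (σ = 0.2, the sole downstream trace of the per-animal
  light titration) and lognormal event jitter (σ = 0.3, so a sizable
  fraction of events is weak, mirroring the ~50% response-rate titration
  goal). The 6:1 evoked-to-background amplitude ratio corresponds to a
  clearly visible visually evoked potential.
- **Cohort effects:** per-trial multipliers only. The standard models
  are US+Light evoked gains (1, 1.5, 1.2); Light-only (1, 0.85, 0.8),
  a slow habituation; US-only evoked gains identically zero with
  background gains (1, 1, 0.85), a post-exposure reduction of ongoing
  activity. The ultrasound itself (acoustics, heating) is deliberately
  not modelled — only its hypothesized effect on amplitudes.
- **Artifacts:** Poisson bursts (0.5/min) with a 0.5-s half-sine
  envelope on an in-band 23 Hz carrier at 20× the background RMS,
  chosen to reliably trip the 4-SD rule, with spans recorded in the
  ground truth so rejection sensitivity and false-rejection rates are
  measurable.
- **Timeline:** the full session (both baselines, a titration gap
  defaulting to the study's mean of 12.29 min, trials, rest) with
  exact 10-s marker spacing. The default sampling rate is 2 kHz rather
  than the acquisition hardware's 20 kS/s: the analysis band ends at
  55 Hz, so 2 kHz retains an 18× Nyquist margin, and 20 kHz is
  supported but wasteful for simulation; titration is emulated as an
  idle gap plus the per-mouse scale draw, not as a closed-loop search,
  because its only downstream effect is per-animal stimulus strength.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data — includes non-stationary anesthesia
depth, correlated multi-channel noise, electrode drift, true evoked
waveform shape (only its duration bound and band location are
constrained by the design), and any acoustic coupling of the ultrasound
into the recording.

## Statistical design choices and limitations

- The pooling unit is the per-event scalar, reproducing the original
  counting (~420 values per cohort-trial). Mice are not modelled as
  random effects, so events from the same animal are treated as
  independent; this replicates the published approach but understates
  between-animal correlation, and cohort-level conclusions should be
  read with that caveat.
- The Trial-1 vs Trial-2 comparison on Trial-1-normalized data is
  slightly anticonservative under the null, because Trial 1 is compared
  against values normalized by its own sample median (simulated type-I
  ≈ 0.075 at α = 0.05 with small cohorts). Trial 2 vs Trial 3 — both
  normalized by the independent Trial-1 reference — is exchangeable
  under the null and calibrated; the package's null-calibration check
  is therefore defined on that comparison.
- Exact Mann–Whitney mode uses the exact U distribution when there are
  no ties and full enumeration of group assignments (midranks) when
  there are; the approximate mode is the tie-corrected normal
  approximation with continuity correction. Enumeration shows the
  approximation tracks the exact two-sided p to within 0.003 wherever
  p < 0.2 and 0.006 globally (worst near p ≈ 0.46) for 15-vs-15
  samples, so the mode switch cannot change a verdict at any of the
  registered thresholds.
- Quantile convention: linear interpolation between order statistics
  (R type 7) for medians, quartiles and the 0.5/99.5-percentile
  whiskers that enclose more than 99% of the data.
- Effect-gain recovery: the trial1-normalized pooled median ratio
  understates a pure evoked-amplitude gain because the envelope
  contains the ongoing-background floor. `estimate_trial_gain()`
  therefore ratios the evoked excess above the (unit) baseline floor on
  the baseline-normalized scale, `(median_T2 − 1)/(median_T1 − 1)` at
  k = 2; on standard synthetic cohorts it recovers gains of 1.2–2.0
  within a few percent.

## Numerical choices

- Envelope computation uses a cumulative-sum moving average, verified
  against a brute-force windowed loop to 1e-10 relative tolerance; edge
  windows are truncated, not padded.
- Filtering pads by odd reflection over 6/low-edge seconds so filter
  start-up transients decay outside the data; the compiled biquad
  cascade matches reference zero-phase filtering to ~1e-6 on unit-scale
  signals.
- Degenerate inputs fail loudly: empty samples, missing references,
  recordings shorter than one rejection window, markers hanging over
  the recording end (dropped with a warning count), and double
  normalization (stage flags make it impossible).
- All randomness flows from explicit seeds; per-mouse seeds derive from
  the master seed, cohort label and mouse index by a deterministic
  string hash, so cohorts are independent and bit-reproducible on any
  platform.

## Problem sizes used in the shipped validation

The package's own test suite runs entirely on synthetic data sized for
a desk machine: most structural checks use 6-event trials at 500 Hz;
event-count checks use full 600-s trials at 500 Hz; the
detection-and-recovery check uses 20 independent 7-mouse US+Light
cohorts with full 10-min trials at 2 kHz (single analysis channel,
shortened idle spans, which do not enter the analysis); the
null-calibration check uses 500 two-mouse sessions with 12-event trials
at 500 Hz, since the level of a rank test does not depend on the signal
scale. The acceptance script (`scripts/acceptance.R`) recomputes the
same quantities at these sizes from a single command-line seed.

## File formats

Sessions are exchanged as BrainVision triples (text `.vhdr` header,
text `.vmrk` markers with 1-based sample positions, IEEE float32
little-endian multiplexed `.eeg`, units µV) inside a BIDS layout with
`participants.tsv`, per-run `events.tsv`, and JSON sidecars for the
segment map (BIDS has no native trial-phase concept at this
granularity) and, for synthetic data, the ground truth. The reader is
permissive about missing sidecars but rejects — never repairs —
malformed headers or truncated binaries. Round-trips are exact to
float32 precision, which at typical ECoG amplitudes (hundreds of µV)
means absolute errors up to a few times 1e-5 µV.
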