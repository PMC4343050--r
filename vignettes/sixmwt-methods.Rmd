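---
title: "Walk-test analysis from trunk inertial signals: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walk-test analysis from trunk inertial signals: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixmwt)
```

## The measurement problem

A 6-minute walk test is performed back and forth on a straight walkway of
known length `L`, with a phone worn backward at the mid lower back
recording tri-axial linear acceleration and azimuth at a nominal 50 Hz
whose instantaneous rate jitters by several Hz. The clinically important
output is total distance walked; the biomechanically interesting outputs
are per-step foot-strike times, left/right labels, cadence and symmetry.

The key structural insight is that the walkway geometry removes the need
for person-specific calibration. Every completed traversal contributes
exactly `L` metres, so distance estimation error is confined to the final
partial walkway, which is estimated as its step count times the mean step
length of a reference traversal (`L` divided by that traversal's step
count). Step-length error therefore never compounds across the test.

## Signal model and pipeline

**Regularization.** All window arithmetic downstream assumes constant
sample spacing, so trials are linearly interpolated onto a uniform grid
(default 50 Hz, the nominal device rate). Linear rather than spline
interpolation avoids overshoot next to the sharp strike transients.
Azimuth is unwrapped into a continuous heading *before* interpolation —
interpolating across the 0/360° seam would manufacture spurious
mid-range values — and re-wrapped for storage.

**Azimuth unwrap.** An inter-sample difference whose magnitude exceeds
`wrap_trigger` is replaced by whichever of `d`, `d − 360`, `d + 360` is
smallest in magnitude. The default trigger is 180°, the geometric point at
which the short way around becomes strictly shorter; a strict-fidelity 10°
trigger is available (`wrap_trigger = 10`) and agrees with the default on
walking data, where genuine rotation rarely reaches 10° per sample at
50 Hz.

**Zero-lag filtering.** Step detection uses a 4th-order Butterworth
low-pass at 4 Hz applied forward and backward (`signal::filtfilt`), so
peaks do not shift in time; laterality uses a 1 Hz version of the same
filter. Lower step-detection cutoffs start to merge adjacent steps.
`signal::filtfilt` starts each pass from zero state, so the ends are
extended by odd reflection before filtering; the pad length is computed
from the filter's slowest pole radius so that start-up transients decay
below 1e-12 inside the pad. This keeps the DC gain exact, preserves
symmetric pulse locations to within a sample, and makes the whole
operation symmetric under time reversal to ~1e-9 — all of which the test
suite asserts. A fixed short pad (e.g. 15 samples) fails all three at this
filter order and rate.

**Turn detection.** Turns trigger where the azimuth range within a 3 s
sliding window exceeds 100° ("range" rather than signed net change, which
is robust to noise sign), and each trigger extends to the maximal
contiguous region whose centred 1 s frames keep an azimuth SD above 10°.
These two scales separate cleanly on plateaus-plus-reversals heading
profiles: plateau frames have SD near the azimuth noise (a few degrees),
turning frames an order of magnitude more. Walkway/turn segments tile the
trial exactly; traversal slivers shorter than 0.5 s (a trial beginning or
ending mid-turn) are kept in the tiling but flagged degenerate and
excluded from calibration and step-length estimation.

**Self-calibration.** The first 5 s of the first usable walkway provide:

* the *locking period* from intervals `Z` between positive-going zero
  crossings of the filtered vertical signal — `max(Z)/2` by default,
  `mean(Z)/2` when `max(Z) > 0.7 s` (crossings were missed),
  `0.6·max(Z)` when `max(Z) < 0.4 s` (extra crossings); the window widens
  in 1 s increments up to 10 s if fewer than 2 crossings are found;
* the detection axis: forward by default, vertical when the
  forward/vertical direction-reversal-count ratio exceeds 1.4 (multi-peak
  forward waveforms);
* a boundary threshold per channel, `max − mean` over the window.

**Step detection.** A window one locking period wide advances through the
detection signal; its maximum, snapped to the local crest apex, is a
candidate. Shape similarity replaces fixed thresholds: the candidate's
`Left_Diff`/`Right_Diff` (peak minus the minimum within one locking
period on each side — the side minima are sought on the waveform itself,
beyond the segment boundary if needed, since the signal does not stop at a
segment label) must each exceed 0.35 of the previous step's values.
Every candidate must also clear an amplitude floor: its peak prominence
(the smaller side difference) must exceed `boundary_fraction` (default
0.65) of the detection channel's boundary threshold. The floor is what
accepts the attenuated first and last steps of each walkway, which have no
usable previous-step reference or reduced amplitude; 0.65 sits midway
between the measured prominence of attenuated boundary steps
(≥ ~0.75 of the threshold) and the prominence tail of filtered noise
(≤ ~0.55 at the highest supported noise level). The floor is compared
against the *matched* channel's threshold because an amplitude criterion
derived from the forward channel is not commensurable with vertical-axis
peaks. After an acceptance the window jumps one locking period past the
peak, enforcing the refractory rule.

**Missed steps and stops.** A gap exceeding 1.75× the previous step
duration is re-searched: an unclaimed local maximum is accepted when its
shape ratios exceed 0.30, its timing continues the prior inter-step
interval within ±25%, and the *other* acceleration channel clears its own
(unscaled) boundary threshold near the candidate. Gaps that remain
unexplained are recorded as stops; stop time is excluded from cadence and
step-time statistics, and stopped walkways are skipped when choosing the
distance reference walkway.

**Foot-strike timing.** The backward-facing phone makes foot strike the
most negative *raw* forward acceleration; each event's strike is the raw
minimum within half a locking period of the filtered peak, ties resolving
to the earlier sample.

**Laterality.** On the 1 Hz mediolateral signal, the tangent at
0.25 of the step duration after foot strike (slope from the central
difference of adjacent samples) is evaluated one locking period before and
after the anchor. The tangent lying strictly above the signal at both
points means the trunk is accelerating rightward (the curve bends away
beneath the tangent); ties classify left. The slope uses adjacent
*samples* while the comparison offsets use the locking period — two
different scales, both honoured. Alternation then repairs the sequence
per walkway (resetting across stops): of the two alternating assignments,
the one whose disagreements carry the smaller summed tangent margin wins,
so confident labels are kept and marginal ones flipped. This equals the
brute-force minimal-margin alternating assignment, which the tests verify
by enumeration on short sequences.

**Outcomes.** Step time is the interval between successive foot strikes
within a walkway (never across turns or stops), attributed to the foot
that lands; stride time joins same-side strikes; cadence is reported per
walkway, as a cross-walkway mean/SD, and as an overall value, all
excluding stop time; the symmetry index is the left/right mean step-time
ratio (an `|L−R|/mean` asymmetry form is available). A side with fewer
than two steps reports `NA`, not zero. SDs are population SDs. The
slowdown rule scales the final walkway's step length by the last/reference
mean-step-duration ratio when that ratio falls below 0.9, using durations
that exclude the first step out of the turn (atypically long).

## The synthetic generator

`gait_scenario()`/`generate_trial()` produce annotated trials whose ground
truth is exact by construction: strikes are scheduled at the cadence with
~0.8% timing jitter; per-step lengths are drawn and rescaled so every
completed walkway sums to exactly `L` (total distance is the exact sum of
scheduled step lengths); turns are constant-rate 180° heading ramps;
sampling times come from a rate drawn per sample at 50 ± 3.84 Hz.

Waveforms emulate a backward-facing phone at the lower back. Each strike
contributes a smooth push-off lobe (2.5 m/s², σ 55 ms) plus a biphasic
transient: a narrow negative shock (12 m/s², σ 20 ms) with a co-centred
rebound of half the depth and twice the width. The equal-area rebound is
what lets the raw channel show a deep, reliably-sampled spike at the
strike while the 4 Hz-filtered channel keeps a single smooth peak per
step — a one-sided spike of that depth would survive filtering and split
the crest. The vertical channel has the same structure, peaking 60 ms
*after* the strike, and rides a negative baseline while walking so it
crosses zero once per step (the baseline envelope extends ~0.8 step
periods past the final strike of a walkway, as trunk oscillation does not
stop instantly). The mediolateral channel receives one stride-frequency
lobe per step whose sign encodes the side. Steps adjacent to turns are
attenuated to 0.85 of normal amplitude — starting and slowing steps have
lower peaks, but remain detectable, consistent with boundary steps being
countable in practice. The atypical archetype adds three alternating
sub-lobes per cycle to the forward channel, producing the multi-peak
pattern that drives axis selection to vertical; their negative lobe is
placed outside the foot-strike search window so timing remains meaningful.

Scripted events: a *stop* pauses the strike schedule (truth contains the
stop interval); a *dropout* flattens the channels while the walker keeps
stepping, hidden strikes staying in the truth. The default dropout is
2.2 s at cadence 125, snapped to the strike schedule so exactly four
strikes are hidden regardless of jitter.

The default suite (`default_scenarios()`) holds 15 seeded scenarios:
twelve typical gaits spanning cadences 100–125 steps/min and step lengths
0.85–0.95 m (distances ~450–615 m), one with a 3 s mid-test stop, one
atypical multi-peak gait, one dropout trial, and one trial ending two
steps after a turn — the hardest case for the final-walkway estimate.
Accelerometer noise is white at 0.15–0.25 m/s² (device-class), azimuth
noise 2°. Each scenario derives its sub-seed from a single master seed.

**What the suite does not emulate.** Real trunk accelerations have
heteroscedastic, gait-phase-locked noise, baseline drift, soft-tissue
resonance and occasional sensor saturation; real turns contain pivot
steps; pathological gaits (shuffling, severe asymmetry) have weak or
multiple strike transients. Passing on this suite demonstrates the
pipeline's mechanics — segmentation, self-calibration, shape-similarity
tracking, recovery, timing, laterality and the distance decomposition —
under realistic timing jitter and noise, not clinical validity for
impaired populations.

## Numerical choices and degenerate inputs

* Ties in the foot-strike argmin resolve to the earlier sample; tangent
  ties classify left; the alternation-repair tie keeps the left-starting
  assignment.
* The locking period is clamped to [2 samples, 1.5 s].
* A trial with no completed walkway falls back to
  `steps × L / max(total steps, 1)` with a prominent warning.
* A turn abutting the trial boundary still yields a positive-length
  (degenerate) walkway so the tiling invariant holds.
* Resampled azimuth is wrapped with a guard against the floating-point
  quirk where `x %% 360` can return exactly 360 for tiny negative `x`.
* Problem sizes: the bundled tests run 2-minute single trials for module
  checks and the full 15 × 6-minute suite (≈ 9,000 steps) once for the
  acceptance checks, a few seconds per trial on a single core.

## Known limitations

* The evaluation is synthetic; no device recordings ship with the package.
* Step detection assumes distinct strike transients; shuffling gait would
  require different waveform evidence.
* The distance model requires a straight walkway of known length — the
  standard test layout, but not free-living walking.
* A single step stranded at the very end of a recording (data cut mid
  gait cycle) may be unlabeled or missed; with sub-second data margins the
  tangent anchor and side minima are truncated.
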