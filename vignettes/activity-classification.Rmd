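---
title: "Methods: adjustable activity classification for thigh-worn accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adjustable activity classification for thigh-worn accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisma)
```

## The model

A tri-axial accelerometer worn on the upper leg measures, on each axis, the
sum of three components: sensor noise, body acceleration (BA) produced by
movement, and gravitational acceleration (GA) whose projection on the
thigh-longitudinal X axis encodes posture — about +1 g when standing
upright, near 0 g when the thigh is horizontal (sitting or lying). The
classifier exploits exactly this structure:

1. a 0.12 s centered moving average suppresses sensor noise;
2. a 4th-order Butterworth high-pass at 1 Hz isolates BA, and a 4th-order
   Butterworth low-pass at 1.25 Hz isolates GA (both applied per axis,
   zero-phase);
3. both branches are segmented on the same grid of non-overlapping windows
   of WS seconds (N = round(WS × rate) samples; a trailing partial window is
   discarded, since the features are defined only over complete windows);
4. per window, the signal magnitude area
   SMA = (Σ over the 3 axes and N samples of |BA|) / WS (in counts per
   second) measures the amount of physical activity, and the per-axis mean
   of GA measures orientation;
5. the decision tree labels a window **dynamic** when SMA ≥ PA Th, else
   **standing** when the (sign-corrected) mean GA on X ≥ SO Th, else
   **sedentary**.

The assumptions are those of the wear location: the sensor is patched on so
it cannot rotate freely, X points toward the hip (an `orientation_sign`
flag handles an inverted sensor), and upright static posture is separated
from reclined static posture purely by the longitudinal gravity component.

## Parameters and defaults

| Parameter | Unit | Default | Meaning |
|---|---|---|---|
| `window_size` (WS) | s | 2 | segmentation window; shorter windows resolve activity transitions better, longer windows average out within-activity variability |
| `pa_threshold` (PA Th) | cps | 7 | SMA level separating dynamic from static windows |
| `so_threshold` (SO Th) | g | 0.8 | longitudinal gravity level separating standing from sedentary; 0.8 g ↔ arccos(0.8) ≈ 36° thigh angle from vertical |
| `ma_window` | s | 0.12 | moving-average noise window (sensor/rate specific) |
| `hp_cutoff`, `lp_cutoff` | Hz | 1.0, 1.25 | BA / GA separation cutoffs |
| `count_scale` | – | 1 | rescales cps to other hardware count conventions |

The defaults WS = 2 s, PA Th = 7 cps, SO Th = 0.8 g are the settings this
kind of classifier arrives at for healthy elderly wearing the sensor on the
upper leg; `algorithm_parameters()` validates all invariants.

**The counts definition.** "Counts" are not a standardized unit across
hardware. Here 1 count ≡ 1 g·s of rectified body acceleration summed over
three axes, so SMA in cps is the window sum divided by the window duration.
This normalization makes cps independent of WS and of sampling rate (up to
discretization): static noise sits well below 1 cps at the default noise
level while walking produces roughly 8–18 cps, so the printed thresholds
(3–12 cps) are meaningful. `count_scale` is a pure multiplier for matching
other conventions.

**Boundary conventions.** Both threshold comparisons are inclusive (≥): a
window exactly at PA Th is dynamic, exactly at SO Th standing. The boundary
has measure zero for real signals; fixing it makes the classifier fully
deterministic and testable.

## Numerical choices

**Zero-phase filtering.** Analysis is offline, so both Butterworth branches
are applied zero-phase: a causal pass would delay BA relative to GA and
misalign the shared window grid. The implementation designs the recursive
coefficients with `signal::butter()` and applies the squared magnitude
response — the exact steady-state response of a forward–backward pass — in
the frequency domain to the signal extended by mirror reflection. This
formulation is exactly linear, exactly zero-phase (a symmetric pulse yields
a symmetric response to machine precision), transparent at DC for the
low-pass and fully DC-rejecting for the high-pass, and free of the edge
artifacts that zero-padded forward–backward implementations introduce. A
`zero_phase = FALSE` switch provides the causal single-pass variant for
comparison. Filter-property tests exclude a 1 s guard band at each end;
classification uses the full output, since edge effects on multi-minute
recordings are confined to the first/last window.

**Moving-average discretization.** The window is `round(ma_window × rate)`
samples, forced odd (3 samples at 25 Hz) so the filter is symmetric; edges
use the shrunken window rather than fabricated padding.

**Realized window duration.** `round(WS × rate)` samples span
`N/rate` seconds, which differs from nominal WS when WS × rate is not an
integer (e.g. 0.5 s at 25 Hz → 12 samples = 0.48 s). Class totals and the
SMA denominator use the realized duration, so classified time plus the
dropped tail reconstructs the recording duration exactly; for every integer
WS on the optimization grids the two coincide.

**Degenerate inputs.** A recording shorter than one window classifies to an
empty series (valid, zero totals); zero gold-standard time in a class makes
PE undefined there, so that (participant, class) is excluded with a warning
rather than imputed; out-of-range (±8 g) samples are hard errors, since
silent clipping would bias SMA downward.

## Validation statistics

Per participant and class, PE = 100 (T_gold − T_algorithm)/T_gold (positive
= underestimation) and APE = |PE|; both are relative, hence comparable
across studies. Group summaries are medians with a distribution-free 95% CI
from binomial order statistics (ranks at the 2.5%/97.5% tails of
Binomial(n, ½); conservative, coverage ≥ 95%). The exact CI needs n ≥ 6;
below that the range is reported with a warning. A nonparametric CI was
chosen because per-participant percentage errors are few and skewed;
medians are the natural center. The ±10% acceptability band is closed.
Bland–Altman limits use mean ± 1.96 SD (sample SD); ICC(2,1) — two-way
random effects, absolute agreement, single measures — is computed from the
two-way ANOVA mean squares.

## Parameter optimization

`optimize_sequential()` mirrors the two-stage procedure such classifiers
are tuned with: sweep WS (default 1–10 s) at the starting parameters
(WS = 1 s, PA Th = 5 cps, SO Th = 0.8 g), then sweep PA Th (default 3–12
cps) at the winning WS. SO Th is never varied: it is fixed by the wear
location, not the population. The combining rule across the three classes
is deliberately explicit, since "smallest classification error" needs one:
the objective is the **sum of the three per-class median APEs** (classes
weighted equally, individual-level errors); a max-class alternative is
selectable. Ties break toward the smaller parameter value — smaller windows
resolve transitions better, and a lower threshold is the more sensitive
choice at equal error. `optimize_joint()` offers the full 2-D grid for
sensitivity analyses; the sequential procedure is the default because its
one-dimensional error profiles remain interpretable.

## What the synthetic generator emulates — and what it does not

`generate_segment()` builds each activity from first principles: a constant
gravity vector (cos θ, 0, sin θ) g set by the thigh angle θ (gravity
confined to the X–Z plane, sufficient because only the X component enters
the classifier), plus — for movement — sinusoids at a gait frequency
(1–2 Hz) and its first harmonic across the axes, plus white Gaussian noise
(default 0.01 g, keeping static SMA well below the smallest threshold on
the sweep grid). Movement amplitude is calibrated empirically: a probe
segment is passed through the package's own moving-average and high-pass
filters and the amplitude scaled so the measured SMA equals the requested
cps (linearity of the filters and positive homogeneity of rectification
make this scaling exact in expectation); calibration results are cached per
(frequency, rate, constants).

`generate_fap()` emulates a fixed protocol — standing 120 s, slow walk
120 s @ 8 cps, sitting 180 s, brisk walk 120 s @ 18 cps, lying 120 s,
overground walk 120 s @ 15 cps, biking 120 s @ 12 cps — giving exactly
480/120/300 s of dynamic/standing/sedentary time. Intensities are
plausibility choices for elderly gait (configurable); durations are
multiples of the default window. `generate_sfp()` emulates free living: a
shuffled class-balanced sequence of ADLs with durations drawn from
20–180 s, dynamic transfers of 5–15 s inserted between consecutive
non-dynamic ADLs, small fidgeting intensities on static ADLs, and a
`mixed_adl` mode that interleaves 2–5 s standing micro-pauses inside blocks
labeled dynamic — reproducing the rater convention of tagging a compound
household task as one dynamic block, which is the dominant source of
dynamic classification error under free living.

What the generator does **not** emulate: biomechanically realistic gait
waveforms (impact transients, stride-to-stride variability), sensor error
models (bias, cross-axis talk, saturation), gradual posture drift, or
observer mislabeling beyond the micro-pause mechanism. Passing tests
therefore demonstrate that the pipeline is internally correct and behaves
as designed under its stated model of the signal — clean gravity/gait-band
separation — not that the error magnitudes transfer to real recordings of
real participants, where intensity distributions are broader and labels
themselves are noisy.

## Problem sizes

The test suite and acceptance script run on cohorts of 10 synthetic
participants (900 s fixed-protocol recordings; free-living recordings of
~12 ADLs, typically 15–25 min) at 25 Hz, parameter sweeps over 10 window
sizes and 10 thresholds, and 5 replicate cohort seeds for the
parameter-recovery check — sizes at which every experiment is exactly
reproducible from one seed while still exercising all code paths at
realistic recording lengths.

## Known limitations

- The cps scale is a convention; absolute threshold values only transfer to
  hardware whose counts match it (use `count_scale` otherwise).
- Sequential optimization can miss a jointly better (WS, PA Th) pair;
  `optimize_joint()` exists for that check.
- The posture rule assumes upper-leg wear; chest or wrist placements need a
  different orientation feature, not just different thresholds.
- Zero-phase filtering is non-causal by construction and unsuitable for
  real-time classification.
- The fidgeting model for static ADLs is sinusoidal; real fidgeting is
  burstier, so static-window SMA variance is likely underestimated.
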