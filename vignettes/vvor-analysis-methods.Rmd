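---
title: "Measuring visually enhanced VOR gain: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring visually enhanced VOR gain: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vvorkit)
```

## The measurement problem

In the visually enhanced vestibulo-ocular reflex (VVOR) test an examiner
oscillates the patient's head sinusoidally at roughly 1–2 Hz, to a peak
velocity of 150–200 deg/s, while the patient fixates an earth-fixed target.
Goggle systems record head and eye angular velocity at a few hundred hertz.
A healthy response is a smooth eye rotation equal and opposite to the head
(gain ≈ 1). Vestibular or combined vestibulo-cerebellar disease reduces the
gain, and the resulting retinal slip elicits catch-up saccades — brief
velocity spikes that interrupt the smooth response and bias any naive
eye/head ratio.

Quantifying the VVOR therefore involves two problems: removing the fast
phases without distorting the slow component, and reducing two quasi-periodic
velocity traces to a directional gain. This vignette describes how
`vvorkit` solves both, the parameters that matter, and exactly what the
validation suite does and does not demonstrate.

## Desaccading with a windowed median

The eye channel is filtered with a one-dimensional median filter of window
length `n = 30` **samples** (`desaccade()`). The window is the classical
asymmetric one for even lengths — output `y(i)` is the median of the raw
samples over `[i − n/2, i + n/2 − 1]` — and the centred window for odd
lengths; the median of an even count of samples is the mean of the two
middle order statistics, fixed so results are bit-reproducible. Edges are
zero-padded by default, reproducing the behaviour of the classical
`medfilt1` routine; a `reflect` mode is offered because it produces a much
smaller edge transient.

A median over a window is robust to any spike that occupies fewer than half
the window's samples: a typical fast phase (30–80 ms, i.e. 7–18 samples at
220 Hz) is simply absent from the output, while the smooth component passes
through. The *residual* — raw minus filtered eye velocity — then isolates
the saccades for counting.

Two consequences of the windowed median are worth knowing:

* **Peak smoothing.** Near a velocity peak the signal is locally
  non-monotone, and the windowed median reports an off-peak quantile. At the
  protocol operating point (1.5 Hz stimulus, 220 Hz sampling, `n = 30`) the
  flattening is about 5% of the amplitude at the exact peak — visible when
  raw and desaccaded traces are overplotted, and the reason recovered
  healthy gains sit near 0.99 rather than 1.000. The artifact grows rapidly
  as the window approaches the stimulus half-period: at 2 Hz and 100 Hz
  sampling a 30-sample window spans 0.3 s and flattens the peak by roughly
  40%. `n` is expressed in samples, exactly as the filter is defined, so its
  effect depends on the sampling rate; the default assumes a ~220 Hz device.
* **Edge transient.** With zero-padding the first and last `n` samples mix
  real data with padding zeros, producing a spurious residual when the
  window starts mid-cycle. The saccade detector therefore ignores peaks in
  the first and last `n` samples; they are filter artifacts, not eye
  movements.

Window selection happens *before* filtering: the first second of the
recording (test onset) is discarded and the following 10 s analysed
(`select_window()`). Ten seconds covers ≥ 10 stimulation cycles at protocol
frequencies while keeping reports insensitive to recording length;
filtering after windowing also keeps the edge transient at known, guarded
positions.

## Two directional gain estimators

Both estimators run on the desaccaded trace after splitting samples by the
sign of head velocity (`split_directions()`); samples with head velocity
exactly zero carry no directional label and are excluded, and each
direction is handled as its contiguous runs (half-cycles).

**Area under the curve** (`auc_gain()`). Head and filtered eye velocity are
integrated run-by-run by the trapezoidal rule over the actual time stamps,
the signed run integrals summed per channel, and

$$G_{AUC} = -\frac{\sum_r \int_r \hat{e}(t)\,dt}{\sum_r \int_r h(t)\,dt}$$

per direction. Integrating run-by-run matters: concatenating the subset
samples into one array before integrating would fabricate trapezoids across
the gaps between half-cycles. The signed eye integral is used as-is (no
absolute value), so an anti-compensatory response yields a negative gain
and is reported as such — the sign distinguishes backup-saccade pathology
from simple hypofunction. The single global negation makes compensatory
responses positive.

**Scatter-plot slope** (`scp_gain()`). Filtered eye velocity is regressed
on head velocity by least squares *through the origin* — the single-column
linear solve $\hat\beta = \sum h e / \sum h^2$ — and the gain is $-\hat\beta$
per direction. Physiologically a zero head velocity demands a zero
compensatory eye velocity, so the no-intercept model is the default; an
intercept variant is exposed (`intercept = TRUE`) for sensitivity analysis
only.

For a noiseless linear response $e = -g\,h$ both estimators return $g$ to
floating-point accuracy, which the test suite pins at relative error
≤ 1e-10 for $g \in \{0.1, 0.45, 0.8, 1.0\}$. They differ only in how they
weight deviations (AUC by time, the slope by head-velocity magnitude), so
their agreement on real-shaped data is an informative cross-check, not a
tautology: the validation battery requires ICC ≥ 0.99 and a maximum
between-method difference ≤ 0.08 gain units, and observes ~0.9999 and
~0.005.

## Frequency, saccade metrics, and agreement statistics

`fft_spectrum()` computes one-sided amplitude spectra (|DFT|·2/N) of both
channels on a rectangular window with no zero-padding — only the argmax is
consumed downstream, so spectral leakage is immaterial and the bin width
(1/duration) stays honest. The dominant frequency is the head-amplitude
argmax over bins above 0.2 Hz (configurable); the floor keeps slow examiner
drift out of the search, and ties break toward the lower frequency. Head
velocity contains no saccades, so raw-versus-desaccaded is immaterial for
the dominant frequency.

`detect_saccades()` finds local maxima of |residual| with height
≥ 30 deg/s and separation ≥ 50 ms (the smaller of two conflicting peaks is
suppressed). The thresholds are physiological defaults — fast phases far
exceed the smooth-response residual, and saccades respect a refractory
interval — exposed as configuration and recorded in every report, since no
universal values exist. Rates use the analysed-window duration
(`per_second`), and `saccades_per_cycle()` divides by the dominant
frequency. With both polarities detected on |residual|, leftward and
rightward fast phases are counted alike and the polarity recorded per
event.

`icc_agreement()` implements the two-way random-effects,
absolute-agreement, single-measure ICC — ICC(2,1) — from the mean squares
of the subjects × methods decomposition, with the F-based 95% interval.
Absolute agreement, not consistency, is the right form when two methods
must be clinically interchangeable; 0.90 is the conventional threshold for
excellent concordance. `bland_altman()` reports bias and 1.96-SD limits of
agreement. The paired unit is one direction of one trace, so each recording
contributes a positive and a negative pair.

## The synthetic generator: what it emulates, and what it does not

`simulate_vvor()` provides ground truth for every stage. Head velocity is a
sinusoid whose half-cycle periods are jittered multiplicatively
(`exp(ε), ε ~ N(0, 0.03)` by default) to mimic manual oscillation; the
smooth eye component is `−g · head` with separate gains by direction; fast
phases are Gaussian velocity pulses (default 150 deg/s peak, 40 ms
duration, i.e. SD = 10 ms) oriented in the catch-up direction for gains
below 1 and the backup direction above 1, placed per half-cycle at
least 30 ms from head zero crossings so that ground truth remains
unambiguous after filtering; white noise (SD 2 deg/s, typical of
video-oculography velocity traces) is added to the eye channel last, so a
seed fixes stimulus and saccade placement at every noise level.

The four presets encode the clinical groups used for validation, with
directional gains, saccade rates and oscillation frequencies at the group
means: healthy (1.00/1.00, 0 saccades/cycle, 1.52 Hz), bilateral
vestibulopathy (0.84/0.82, 3, 1.0 Hz), unilateral hypofunction (0.85 intact
side / 0.69 lesioned side, 2, 1.76 Hz), and CANVAS (0.45/0.40, 4, 1.35 Hz).

The generator deliberately omits: ocular-plant dynamics and saccade
main-sequence kinematics (pulses are symmetric Gaussians), pupil-tracking
artifacts and blinks, the cervico-ocular and optokinetic contributions to
the response, and any gain dependence on frequency. Passing the validation
battery therefore shows that the *estimators* recover known parameters from
realistically shaped, noisy, saccade-laden traces — it does not certify
behaviour on device data with artifact classes the generator does not
produce (above all blinks, which the pipeline does not reject).

## Validation battery and problem sizes

The test suite runs, among others: exact-recovery checks at 1e-10 on
noiseless linear responses; 50 healthy replicates (20 s at 220 Hz each)
requiring mean G_AUCp within ±0.03 of 1.00 and every directional gain
≥ 0.95; a 35-trace battery mixing the presets in clinical proportions
(10/12/8/5) requiring between-method ICC ≥ 0.99 and max |difference|
≤ 0.08; zero detected saccades on every healthy replicate; per-preset mean
gain recovery within ±0.05 over 50 replicates with exact matching of
injected saccades to detections; and brute-force oracles (explicit
sort-and-middle median, hand-summed trapezoids, O(N²) DFT, hand-computed
ANOVA mean squares) against every numerical core. `scripts/acceptance.R`
re-runs the headline batteries from scratch at any seed.

Systematic residual effects worth knowing when reading results: healthy
recovered gains centre near 0.988, not 1.000 (peak smoothing, above), and
CANVAS-preset gains centre ~0.03 above truth because with four fast phases
per cycle the pulse tails overlap within single filter windows and a small
compensatory-direction remnant survives filtering. Both biases are well
inside the ±0.03/±0.05 validation bands and are properties of the median
filter itself, not of the implementation.

## Degenerate inputs and numerical conventions

* A direction with no run of ≥ 2 samples, or with |Σ head integral| below
  1e-9, raises a degenerate-direction error naming the direction — gains
  are never silently `NaN`.
* Recordings shorter than 2 s are refused; shorter-than-requested windows
  fall back to the full post-discard trace with a warning.
* Rows with unparseable numerics are dropped (count reported); a sampling
  gap longer than 5 nominal intervals splits the block and only the final
  segment is analysed, with a warning.
* Reports are written with 17-significant-digit floats in a fixed key
  order: identical input and configuration give byte-identical files, and
  every number re-parses to its exact binary value.
* Zero detected saccades is a valid outcome, reported as 0 (not missing).

## Limitations

Laterality is configuration, not inference: devices disagree on the sign of
rightward head movement, so outputs are labelled "positive/negative
direction" unless the user asserts `invert_head`/`invert_eye` and supplies
labels. The package computes no combined left/right gain and no
group-comparison statistics; it measures single recordings and quantifies
method agreement.
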