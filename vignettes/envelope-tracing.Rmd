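---
title: "Adaptive envelope tracing for transcranial Doppler spectrograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive envelope tracing for transcranial Doppler spectrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcdenv)
```

## The estimation problem

Pulsed Doppler ultrasound measures the velocity distribution of red blood
cells in a sample volume: the demodulated echo signal `IQ[·]` is a complex
time series whose instantaneous frequency content maps to scatterer velocity
through

  v = Δf · c / (2 f_c cos α),

with `c = 1540` m/s the assumed tissue sound speed, `f_c` the carrier
frequency and `α` the insonation angle (0° is the standard assumption for
MCA and ICA examinations, where the true angle is small). At the default
acquisition (1.75 MHz carrier, 6.944 kHz echo sampling) the maximal
detectable shift of 3.472 kHz corresponds to about 152 cm/s.

The clinically relevant quantity is the *maximal* velocity at each instant —
the upper edge of the time–velocity spectrogram. Estimating it is hard
because the edge region has the lowest SNR in the image, the SNR drifts as
the probe and patient move, and probe slippage causes outright signal loss.
The estimator implemented here couples a family of binary segmentations to a
beat-by-beat physiological quality score and lets the quality score pick the
segmentation, which removes the need for any per-recording calibration.

## Pipeline stages and their parameters

**Wall filter.** Vessel-wall reverberation concentrates below ~100 Hz; a
second-order Butterworth high-pass at 100 Hz removes it. Because processing
is offline, the filter runs forward–backward (zero phase). Two passes square
the magnitude response, so the effective attenuation at the cutoff is −6 dB.
The implementation absorbs filter transients in odd-reflection padding and
restores the (filtered) mean scaled by the squared DC gain, so constants are
handled exactly.

**STFT geometry.** Hop 1/217 s, window 4 hops (≈18.4 ms, 75% overlap), Hann
taper, zero-padded to 1024 FFT bins. Frames are centered on the hop grid
with zero-padded edges, so one second of echo yields exactly 217 columns and
the envelope inherits a 217 Hz sampling rate; the velocity resolution is
Δv ≈ 0.298 cm/s. A window-count convention based on fully interior windows
would yield 214 columns per second and break the 217 Hz alignment used by
everything downstream, which is why the centered convention was chosen. The
taper and FFT length are conventional PSD choices; both are configurable and
nothing downstream depends on them structurally.

**Log-compression.** Displayed intensity is
`clip(1 + 10·log10(P/P_max)/D, 0, 1)` with dynamic range `D = 40` dB: the
brightest pixel maps to exactly 1, anything ≥ 40 dB down maps to 0. This is
the standard ultrasound display mapping and makes "intensity" a
device-independent quantity in `[0, 1]`, which is what makes an Otsu
threshold on it meaningful.

**Flow-region selection.** The signal can sit at positive (MCA) or negative
(ICA) velocities. The side with the larger summed intensity in the
5–125 cm/s magnitude band wins; the band starts at 5 cm/s to exclude the
wall-filter stop band. Exact ties resolve to the positive side. All
processing after this point happens on velocity magnitudes (negative-flow
images are flipped), and the sign is restored on output. Sign-crossing
(reverse) flow is out of scope by construction.

**Otsu grid.** Otsu's threshold minimizes the within-class variance of the
256-bin intensity histogram of the flow band, by exhaustive scan over bin
edges (ties to the smaller threshold; 256 bins is the 8-bit convention — the
bin count is configurable). Segmentation at `γ_Otsu` alone tends to clip the
systolic peaks, so a multiplicative grid `{0.9, 0.95, 1, 1.05, 1.1}·γ_Otsu`
is traced in full and the quality loop arbitrates. Binarization uses `≥`, so
threshold 0 deterministically marks everything as signal.

**Despeckle.** A 2D median filter with a 0.03 s × 5 cm/s kernel, converted
to odd pixel counts (7 × 17 at the defaults, rounding to the nearest odd so
the median is centered), boundary by edge replication. On a binary image
this is a majority vote, implemented with an integral image.

**Tracer.** Per column, the top five white pixels scanned downward from
152 cm/s are candidates. A candidate is accepted if (1) strictly more than
half of the 40 bins (≈12 cm/s) below it are white — isolated speckle has no
such support — and (2) it deviates at most 30 cm/s from the mean of the
previous three accepted values (≈14 ms of history). Bins below the band
floor count as white in check 1 so that genuine low-velocity edges near the
stop band are not starved of support. If no candidate passes, the previous
value is held; when that has happened for more than 20 consecutive columns
the maximal candidate is taken regardless and the failure counter resets,
letting the trace re-anchor after genuine level shifts. The first three
columns skip check 2 (no history yet); the very first value is the highest
candidate with support, else 0. A column with no candidates at all while the
counter is saturated keeps holding — there is nothing to re-anchor to.

**Onset detection.** The quality stage needs beat onsets. The detector is a
slope-sum-function (SSF) realization of the standard arterial-pulse onset
approach: the envelope is linearly rescaled so its mean per-beat peak is
near 140 (the amplitude range such detectors were tuned for, in mmHg), the
SSF is the 128 ms running sum of the positive slope, and an adaptive
threshold — half the median of the last eight SSF peak heights, seeded from
the first two seconds — triggers detection with a 250 ms refractory period.
Each trigger is backtracked to the *last* point of the preceding envelope
minimum plateau, i.e. the foot of the upstroke; taking the last rather than
first minimum point keeps onsets accurate when the diastolic tail is flat
(as it is during signal loss). Rescaling affects detection only, never the
reported velocities, which also makes detection scale invariant.

**Beat screens and template matching.** Four screens per beat: systolic
max > 30 cm/s, pulsatility > 20 cm/s, duration within (0.25 s, 2 s) (heart
rate 30–240 bpm) and within (0.5, 2)× the segment's median duration. The
screen-passing beats are zero-padded to the longest one, the pointwise
median is the beat template, truncated to the median valid-beat length.
Each passing beat's MSE against the template is computed on the first 75% of
the template duration (heart-rate variability mainly stretches the diastolic
tail) and normalized by the template's mean square over the same window —
the normalization makes 30% a scale-free artifact cutoff. Screen-failed
beats get SQI 0, are excluded from the template and the NMSE comparison set,
but stay in the artifact-index denominator: a segment where half the beats
fail screening should not look pristine because the survivors match each
other. No beat alignment or warping is applied.

**Selection and post-processing.** Per segment the candidate with the
smallest artifact index wins; ties resolve to the threshold nearest
`γ_Otsu`, then to the smaller threshold (prefer the less aggressive
segmentation). The winning raw envelope is low-pass filtered (4th-order
Butterworth, 16 Hz, zero-phase — flow physiology lives well below 16 Hz)
and then passed through a 3-sample median filter, in that order. A
single-sample outlier therefore reaches the median stage already smeared by
the low-pass and is suppressed rather than removed exactly; the tests assert
the achieved ≥75% suppression rather than an idealized median-only account.
Segments are non-overlapping 60 s windows (adapting the threshold to slow
intensity drift); a final remainder shorter than 10 s is merged into the
previous window. Each beat belongs to the segment containing its onset;
samples before the first or after the last onset inherit the nearest beat's
SQI.

## The MTCM baseline

The modified threshold crossing method slides a group of 10 bins from the
high-velocity (noise) end of each column toward zero and stops at the first
group in which at least 5 bins exceed a preset threshold; the envelope is
that group's highest-velocity bin. The group constants are configurable (the
classical literature varies on them) and the threshold is deliberately a
user parameter: its sensitivity to the spectrogram's SNR is exactly the
weakness the adaptive pipeline removes, so automating it would reproduce the
proposed method rather than the baseline.

## Agreement metrics

For an estimate `v_algo` and reference `v_man` of equal length, the error
`e = v_algo − v_man` is summarized by its mean `m_e`, *population* standard
deviation `σ_e` (divide by N, matching the printed definitions), and
relative error `r_e = Σe / Σv_man`. Per-beat peak-systolic differences are
summarized the same way, with Bland–Altman pairs exported. Negative-flow
references are sign-flipped (together with the estimate) before comparison;
a mixed-sign reference errors out. For peak comparison, beats detected
independently in both traces are paired by nearest onset within 0.3 s,
one-to-one; unmatched beats are excluded and counted.

## The synthetic scene generator

The generator produces the conditions the estimator assumes, with ground
truth retained. Per beat (duration from a normal heart-rate distribution,
floored at 0.3 s): a raised-cosine systolic upstroke over the first 15% of
the beat to PSV, an exponential decay renormalized to end exactly at EDV
(so joins are continuous and the per-beat extrema equal PSV/EDV by
construction), plus a Gaussian dicrotic bump (15% of the pulse amplitude at
40% of the beat). The spectrogram is rendered as a uniform-power plateau
from 5 cm/s to the envelope — the laminar-flow approximation — with a
sigmoid edge whose 10–90% rolloff spans the broadening width, an
exponentially distributed noise floor at the configured edge SNR, salt
speckle, and optional dropout intervals that attenuate the signal power
before log-compression. The optional IQ synthesis draws scatterer
velocities from the same per-block distribution, maps them through the
inverse Doppler equation, and sums random-phase complex exponentials plus
complex white noise.

Defaults, chosen once as typical clean-examination values: MCA 90/40 cm/s
and ICA 60/25 cm/s (PSV/EDV), heart rate 60 ± 3 bpm, edge SNR 20 dB,
broadening width 2 cm/s (mild spectral broadening, comparable to the edge
localization a human tracer achieves on a clean window), speckle probability
0.002, dropout preset 2–4 s at power attenuation 0.02 (≈ −17 dB). All
randomness flows from the single scene seed; scenes are bit-reproducible.

What the generator does *not* emulate: intrinsic spectral broadening that
varies with velocity, aliasing, angle drift, slow SNR trends within a
segment, ectopic beats, and genuine reverse flow. Passing the recovery tests
therefore demonstrates correctness of the estimation machinery under the
stated model, not clinical performance on real recordings — the latter
requires reference tracings, for which the `evaluate` route exists.

## Numerical and degenerate-input choices

* Constant-intensity Otsu input returns the constant with a degeneracy
  warning; an all-zero threshold grid is flagged; a zero-power spectrogram
  is an error (normalization undefined).
* Flow-region energy ties break positive; selection ties break toward
  `γ_Otsu`, then the smaller threshold; Otsu's scan ties break toward the
  smaller threshold.
* Zero-phase filtering uses odd-reflection padding (3 time constants,
  minimum 27 samples) so segment edges are not distorted by filter
  transients; the spectrogram CSV container prints 17 significant digits
  and the binary container stores raw float64, both round-tripping
  bit-exactly.
* Windows with no usable beats (all candidates fully artifactual) are still
  emitted, flagged sample-wise, with velocities from the best available
  candidate — downstream consumers decide what to do with them.

## Problem sizes in the test-suite

The unit and property tests run on constructed masks and short scenes
(8–20 s); the end-to-end recovery checks use the full 60 s presets; the
noise-monotonicity property uses 10 s scenes at three SNR levels × 6 seeds.
These sizes were chosen to exercise every rule (including the 20-column
override and segment splitting at 60 s + 10 s remainders) while keeping the
default suite in the low minutes.

## Known limitations

* No sub-bin edge interpolation: the raw envelope is quantized at
  Δv ≈ 0.3 cm/s (the post filter smooths but cannot un-bias this).
* Thresholding a broadened edge sits systematically a little above or below
  the half-power point depending on the noise floor, so a small waveform
  bias of order 1 cm/s on synthetic scenes is expected, not a defect.
* Streaming / warm-started thresholds across segments are out of scope;
  processing is per-segment offline.
* Reverse (sign-crossing) flow cannot be represented after region selection.
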