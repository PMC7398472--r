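# tcdenv

Calibration-free tracing of the **maximal blood flow velocity waveform** (the
envelope) in transcranial Doppler (TCD) ultrasound spectrograms, with a
beat-by-beat **signal quality index**.

## The problem

TCD insonation of the middle cerebral artery (MCA) or internal carotid artery
(ICA) produces a time–velocity spectrogram `SP[t, v]` whose upper edge — the
fastest-moving blood in the sample volume — is the clinically used quantity
(pulsatility and resistivity indices, vasospasm screening, non-invasive
intracranial-pressure estimation all consume it). TCD spectrograms have low
and time-varying SNR, so a fixed intensity threshold cannot separate signal
from noise reliably, and hand tracing does not scale.

`tcdenv` implements an adaptive, fully unsupervised estimator built around a
feedback loop between image segmentation and physiological signal quality:

1. **Spectrogram** — the demodulated complex echo `IQ[·]` is wall-filtered
   (2nd-order Butterworth high-pass, 100 Hz, zero-phase), transformed with a
   short-time Fourier transform (hop 1/217 s, 75% overlap, 1024-point FFT),
   log-compressed to `[0, 1]`, and mapped to velocity via the Doppler
   equation `v = Δf·c / (2 f_c cos α)` — about 152 cm/s at the Nyquist shift
   for a 1.75 MHz carrier.
2. **Segmentation grid** — the signal-carrying flow side (±5–125 cm/s) is
   selected by band energy; Otsu's threshold `γ_Otsu` is computed on that
   band and a multiplicative grid
   `Γ = {0.9, 0.95, 1, 1.05, 1.1}·γ_Otsu` of binary segmentations is formed,
   each despeckled with a 0.03 s × 5 cm/s 2D median filter.
3. **Envelope tracing** — per column, the top five white pixels (scanned down
   from 152 cm/s) are tested against two sanity checks: a majority of the 40
   bins (≈12 cm/s) below the candidate must be white, and the candidate may
   not deviate more than 30 cm/s from the mean of the previous three samples
   (≈14 ms). If no candidate passes, the previous value is held; after more
   than 20 consecutive failures the maximal candidate is taken regardless.
4. **Beat quality** — beat onsets are detected with a slope-sum-function
   detector; each beat faces four screens (systolic max > 30 cm/s,
   pulsatility > 20 cm/s, duration in (0.25 s, 2 s) and within (0.5, 2)× the
   segment median). A median beat template is built from the surviving
   beats; a beat whose normalized MSE against the first 75% of the template
   exceeds 30% is an artifact. Per beat, `SQI = 100·max(0, 1 − NMSE)`.
5. **Selection and post-processing** — per 60 s segment, the candidate
   envelope with the smallest **artifact index** (% flagged beats) wins, then
   a zero-phase 4th-order 16 Hz Butterworth low-pass and a 3-sample median
   filter are applied and the flow sign restored.

The package also ships the classical **modified threshold crossing method**
(MTCM) as a baseline, the waveform/peak agreement metrics
(bias `m_e`, population error SD `σ_e`, relative error `r_e`, and their
per-beat peak-systolic counterparts with Bland–Altman pairs), and a seeded
**synthetic scene generator** (MCA-like, ICA-like, low-SNR and signal-dropout
presets) that retains its ground truth for parameter-recovery testing.

## Worked example

```r
library(tcdenv)

scene <- simulate_scene("mca", seed = 42)   # 60 s, PSV 90 / EDV 40 cm/s
env   <- estimate_envelope(scene$spectrogram)
env
#> <tcd_envelope> 60.0 s at 217 Hz | 1 segment(s), 59 beats | mean SQI 99.9% | artifact index 0.0%

env$candidates
#> # A tibble: 5 × 5
#>   segment_id gamma artifact_index n_beats selected
#>        <int> <dbl>          <dbl>   <int> <lgl>
#> 1          1 0.629              0      59 FALSE
#> 2          1 0.664              0      59 FALSE
#> 3          1 0.699              0      59 TRUE
#> 4          1 0.734              0      59 FALSE
#> 5          1 0.769              0      59 FALSE

evaluate_envelope(env$trace$velocity_cm_s, scene$true_envelope)
#> <tcd_eval> N = 13020 samples: bias 1.07 cm/s, sd 0.17 cm/s, rel 1.99%
#>            59 paired beats: peak bias -0.06 cm/s, sd 0.10 cm/s, rel -0.07%
```

The candidate table shows the feedback loop at work: all five thresholds of
the Otsu grid are traced and scored, and the one with the smallest artifact
index is selected (ties resolve to the Otsu threshold itself, as here on a
clean scene). The evaluation against the retained ground truth shows a
sub-bin peak-systolic bias and a ~1 cm/s whole-waveform bias, the expected
signature of thresholding a spectrally broadened edge.

`tidy(env)` returns the per-beat table (onset, duration, screen outcome,
NMSE, SQI, artifact flag); `glance(env)` a one-row summary; `autoplot(env)`
the envelope colored by SQI; `autoplot(scene$spectrogram)` the spectrogram.

A command-line interface wrapping the same functions is installed at
`inst/cli/tcdenv`:

```sh
Rscript inst/cli/tcdenv simulate --preset mca --seed 7 --out scene/
Rscript inst/cli/tcdenv trace --input scene/spectrogram.csv --format csv \
        --out-envelope envelope.csv --out-report report.json
Rscript inst/cli/tcdenv evaluate --estimate envelope.csv \
        --reference scene/truth.csv --out eval.json
Rscript inst/cli/tcdenv mtcm --input scene/spectrogram.csv --format csv \
        --threshold 0.75 --out mtcm.csv
```

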