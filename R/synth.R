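#' Synthetic Doppler scene settings
#'
#' Parameters of the seeded scene generator used for fixture-based testing
#' and parameter recovery. A scene is a ground-truth maximal-velocity
#' waveform (per beat: raised-cosine systolic upstroke to `psv`, exponential
#' decay back to `edv` with an additive Gaussian dicrotic bump, continuous at
#' beat joins) rendered into a spectrogram: a uniform-power velocity plateau
#' from the wall-filter floor up to the envelope with a sigmoid edge rolloff,
#' an exponentially distributed noise floor at the configured edge SNR, salt
#' speckle, and optional signal-loss (dropout) intervals.
#'
#' @param duration Scene length, seconds.
#' @param heart_rate Mean heart rate, bpm.
#' @param heart_rate_sd Between-beat heart-rate standard deviation, bpm.
#' @param psv,edv Peak-systolic and end-diastolic velocity, cm/s
#'   (`psv > edv > 0`).
#' @param dicrotic_frac Dicrotic bump amplitude, fraction of `psv - edv`.
#' @param dicrotic_time_frac Bump center, fraction of the beat duration.
#' @param dicrotic_width_frac Bump standard deviation, fraction of the beat
#'   duration.
#' @param flow_sign `+1` (toward probe, MCA-like) or `-1` (away, ICA-like).
#' @param edge_snr_db Ratio of signal-plateau to noise-floor power, dB.
#' @param broadening_width Spectral edge broadening: the 10-90% span of the
#'   intensity rolloff across the envelope, cm/s.
#' @param speckle_prob Probability that a pixel is replaced by full-power
#'   salt speckle.
#' @param dropouts `NULL` or a data frame with columns `start`, `length`
#'   (seconds) and `attenuation` (signal power multiplier in the interval).
#' @param seed Integer seed; all scene randomness flows from it.
#' @param rate Envelope sampling rate, Hz (matches the spectrogram column
#'   rate).
#' @return An object of class `tcd_scene_config`.
#' @export
scene_config <- function(duration = 60, heart_rate = 60, heart_rate_sd = 3,
                         psv = 90, edv = 40, dicrotic_frac = 0.15,
                         dicrotic_time_frac = 0.4, dicrotic_width_frac = 0.04,
                         flow_sign = 1, edge_snr_db = 20,
                         broadening_width = 2, speckle_prob = 0.002,
                         dropouts = NULL, seed = 1, rate = 217) {
  if (psv <= edv || edv <= 0) abort("need psv > edv > 0")
  if (duration <= 2 * 60 / heart_rate) {
    abort("duration must cover at least two beats")
  }
  stopifnot(flow_sign %in% c(-1, 1))
  if (!is.null(dropouts)) {
    stopifnot(all(c("start", "length", "attenuation") %in% names(dropouts)))
  }
  structure(
    list(duration = duration, heart_rate = heart_rate,
         heart_rate_sd = heart_rate_sd, psv = psv, edv = edv,
         dicrotic_frac = dicrotic_frac,
         dicrotic_time_frac = dicrotic_time_frac,
         dicrotic_width_frac = dicrotic_width_frac, flow_sign = flow_sign,
         edge_snr_db = edge_snr_db, broadening_width = broadening_width,
         speckle_prob = speckle_prob, dropouts = dropouts,
         seed = as.integer(seed), rate = rate),
    class = "tcd_scene_config"
  )
}

#' Preset scene configurations
#'
#' `"mca"`: positive flow, PSV 90 / EDV 40 cm/s at 20 dB edge SNR.
#' `"ica"`: negative flow, PSV 60 / EDV 25 cm/s.
#' `"low-snr"`: the MCA scene at 10 dB.
#' `"dropout"`: the MCA scene with a 2 s signal loss from 2 s to 4 s.
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [scene_config()].
#' @return A `tcd_scene_config`.
#' @export
scene_preset <- function(preset = c("mca", "ica", "low-snr", "dropout"),
                         seed = 1, ...) {
  preset <- match.arg(preset)
  base <- switch(
    preset,
    "mca" = list(),
    "ica" = list(psv = 60, edv = 25, flow_sign = -1),
    "low-snr" = list(edge_snr_db = 10),
    "dropout" = list(dropouts = data.frame(start = 2, length = 2,
                                           attenuation = 0.02))
  )
  do.call(scene_config, modifyList(base, c(list(seed = seed), list(...))))
}

#' Generate the ground-truth envelope of a scene
#'
#' Beat durations are drawn from the configured heart-rate distribution
#' (floored at 0.3 s); each beat starts and ends exactly at `edv`, so joins
#' are continuous, and its maximum equals `psv`.
#'
#' @param cfg [scene_config()] object.
#' @return A list with `envelope` (cm/s magnitudes at `cfg$rate`), `onsets`
#'   (sample index of each beat start) and `times` (seconds).
#' @export
generate_true_envelope <- function(cfg) {
  stopifnot(inherits(cfg, "tcd_scene_config"))
  set.seed(cfg$seed)
  n <- round(cfg$duration * cfg$rate)
  times <- (seq_len(n) - 1L) / cfg$rate

  starts <- 0
  while (sum_durations(starts) < cfg$duration) {
    hr <- stats::rnorm(1, cfg$heart_rate, cfg$heart_rate_sd)
    dur <- max(0.3, 60 / max(hr, 1))
    starts <- c(starts, starts[length(starts)] + dur)
  }
  onsets_t <- starts[-length(starts)]
  durs <- diff(starts)

  env <- numeric(n)
  onset_idx <- integer(0)
  for (b in seq_along(onsets_t)) {
    idx <- which(times >= onsets_t[b] & times < onsets_t[b] + durs[b])
    if (length(idx) == 0L) next
    onset_idx <- c(onset_idx, idx[1])
    env[idx] <- beat_waveform(times[idx] - onsets_t[b], durs[b], cfg)
  }
  list(envelope = env, onsets = onset_idx, times = times)
}

sum_durations <- function(starts) starts[length(starts)]

# One beat: raised-cosine upstroke over the first 15% of the beat, then an
# exponential decay renormalized to end exactly at edv, plus a Gaussian
# dicrotic bump.
beat_waveform <- function(t, dur, cfg) {
  tr <- 0.15 * dur
  tau <- 0.2 * dur
  amp <- cfg$psv - cfg$edv
  up <- t < tr
  v <- numeric(length(t))
  v[up] <- cfg$edv + amp * (1 - cos(pi * t[up] / tr)) / 2
  td <- t[!up] - tr
  span <- dur - tr
  decay <- (exp(-td / tau) - exp(-span / tau)) / (1 - exp(-span / tau))
  bump <- cfg$dicrotic_frac * amp *
    exp(-((t[!up] - cfg$dicrotic_time_frac * dur)^2) /
          (2 * (cfg$dicrotic_width_frac * dur)^2))
  v[!up] <- cfg$edv + amp * decay + bump
  v
}

#' Render a ground-truth envelope into a spectrogram
#'
#' Builds the linear-power image (plateau from 5 cm/s up to the envelope with
#' a sigmoid edge, dropout attenuation, exponential noise floor, salt
#' speckle), mirrors it for negative flow, and applies the same
#' log-compression mapping as [compute_spectrogram()].
#'
#' @param truth Output of [generate_true_envelope()].
#' @param cfg [scene_config()] object.
#' @param acq [acquisition_params()] object.
#' @param stft [stft_config()] object (velocity axis geometry).
#' @return A [new_spectrogram()] object.
#' @export
render_spectrogram <- function(truth, cfg, acq = acquisition_params(),
                               stft = stft_config()) {
  set.seed(cfg$seed + 1L)
  env <- truth$envelope
  nfft <- stft$fft_bins
  half <- nfft %/% 2L
  fs <- acq$echo_sampling_rate
  vels <- freq_to_velocity((seq_len(nfft) - 1L - half) * fs / nfft, acq)
  if (max(env) >= max(vels)) abort("envelope exceeds the detectable velocity")

  w <- cfg$broadening_width / (2 * log(9))   # 10-90% span = broadening_width
  pos <- vels[vels > 0]
  sig <- 1 / (1 + exp(outer(pos, env, "-") / w))
  sig[pos < 5, ] <- 0

  if (!is.null(cfg$dropouts)) {
    for (i in seq_len(nrow(cfg$dropouts))) {
      d <- cfg$dropouts[i, ]
      cols <- truth$times >= d$start & truth$times < d$start + d$length
      sig[, cols] <- sig[, cols] * d$attenuation
    }
  }

  pwr <- matrix(0, nrow = nfft, ncol = length(env))
  if (cfg$flow_sign > 0) {
    pwr[vels > 0, ] <- sig
  } else {
    # mirror: the negative row whose magnitude matches a positive row (same
    # bin spacing) receives that row's signal
    mag_rows <- rev(which(vels < 0))   # ascending magnitudes
    k <- min(length(mag_rows), nrow(sig))
    pwr[mag_rows[seq_len(k)], ] <- sig[seq_len(k), , drop = FALSE]
  }
  noise_mean <- 10^(-cfg$edge_snr_db / 10)
  pwr <- pwr + matrix(stats::rexp(length(pwr), rate = 1 / noise_mean),
                      nrow = nfft)
  if (cfg$speckle_prob > 0) {
    salt <- stats::runif(length(pwr)) < cfg$speckle_prob
    pwr[salt] <- pmax(pwr[salt], 1)
  }

  p_max <- max(pwr)
  intensity <- pmin(pmax(1 + 10 * log10(pwr / p_max) / stft$dynamic_range,
                         0), 1)
  dim(intensity) <- dim(pwr)
  new_spectrogram(intensity, truth$times, vels, acq)
}

#' Synthesize an IQ signal from a ground-truth envelope
#'
#' Scatterer-ensemble model: per short block, the signal is a sum of
#' random-phase complex exponentials whose frequencies are drawn from the
#' per-block velocity distribution (uniform from 5 cm/s up to the envelope,
#' with logistic edge broadening) mapped through the inverse Doppler
#' equation, plus complex white noise at the configured SNR.
#'
#' @param truth Output of [generate_true_envelope()].
#' @param cfg [scene_config()] object.
#' @param acq [acquisition_params()] object.
#' @param n_scatterers Complex exponentials per block.
#' @return An [iq_signal()] object of length `duration * echo_sampling_rate`.
#' @export
synthesize_iq <- function(truth, cfg, acq = acquisition_params(),
                          n_scatterers = 48) {
  set.seed(cfg$seed + 2L)
  fs <- acq$echo_sampling_rate
  n <- round(cfg$duration * fs)
  block <- max(1L, round(fs / cfg$rate))
  n_blocks <- ceiling(n / block)
  w <- cfg$broadening_width / (2 * log(9))
  v_cap <- 0.98 * freq_to_velocity(fs / 2, acq)

  out <- complex(n)
  for (b in seq_len(n_blocks)) {
    i0 <- (b - 1L) * block + 1L
    i1 <- min(b * block, n)
    env_b <- truth$envelope[min(b, length(truth$envelope))]
    v <- 5 + (max(env_b, 6) - 5) * stats::runif(n_scatterers) +
      stats::rlogis(n_scatterers, 0, w)
    v <- pmin(pmax(v, 0), v_cap)
    f <- velocity_to_freq(v, acq)
    phi <- stats::runif(n_scatterers, 0, 2 * pi)
    t_idx <- i0:i1
    ph <- outer(2 * pi * f / fs, t_idx) + phi
    out[t_idx] <- colSums(exp(1i * ph)) / sqrt(n_scatterers)
  }
  sd_n <- sqrt(10^(-cfg$edge_snr_db / 10) / 2)
  out <- out + complex(real = stats::rnorm(n, 0, sd_n),
                       imaginary = stats::rnorm(n, 0, sd_n))
  iq_signal(out, fs, acq)
}

#' Generate a complete synthetic scene
#'
#' @param cfg [scene_config()] or a preset name for [scene_preset()].
#' @param seed Seed override (used with a preset name).
#' @param iq Also synthesize the IQ signal (slower).
#' @param acq,stft Acquisition and STFT geometry.
#' @return An object of class `tcd_scene`: `config`, `true_envelope`
#'   (magnitudes, cm/s), `true_onsets`, `times`, `spectrogram`, and
#'   optionally `iq`.
#' @export
simulate_scene <- function(cfg = "mca", seed = 1, iq = FALSE,
                           acq = acquisition_params(), stft = stft_config()) {
  if (is.character(cfg)) cfg <- scene_preset(cfg, seed = seed)
  truth <- generate_true_envelope(cfg)
  sp <- render_spectrogram(truth, cfg, acq, stft)
  structure(
    list(config = cfg, true_envelope = truth$envelope,
         true_onsets = truth$onsets, times = truth$times, spectrogram = sp,
         iq = if (iq) synthesize_iq(truth, cfg, acq) else NULL),
    class = "tcd_scene"
  )
}

#' @export
print.tcd_scene <- function(x, ...) {
  cat(sprintf(
    "<tcd_scene> %.0f s | PSV %.0f / EDV %.0f cm/s | sign %+d | %d beats | seed %d\n",
    x$config$duration, x$config$psv, x$config$edv, x$config$flow_sign,
    length(x$true_onsets), x$config$seed))
  invisible(x)
}
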