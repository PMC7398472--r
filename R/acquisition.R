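#' Pulsed-Doppler acquisition parameters
#'
#' Bundles the physical constants of the insonation that enter the Doppler
#' equation: carrier frequency, assumed speed of sound in tissue, insonation
#' angle, and the sampling rate of the demodulated echo signal. The defaults
#' correspond to a 1.75 MHz transcranial probe sampled at 6.944 kHz, for which
#' the maximal detectable flow velocity is about 152 cm/s.
#'
#' @param carrier_freq Carrier frequency of the emitted pulse, Hz.
#' @param sound_speed Assumed average speed of sound in tissue, m/s.
#' @param insonation_angle Angle between beam and flow direction, degrees.
#'   Must lie in `[0, 90)`. With no angle information, 0 is the conventional
#'   assumption for the middle cerebral and internal carotid arteries.
#' @param echo_sampling_rate Sampling rate of the demodulated IQ signal, Hz.
#'
#' @return An object of class `tcd_acquisition`.
#' @examples
#' acq <- acquisition_params()
#' freq_to_velocity(3472, acq) # ~152.8 cm/s
#' @export
acquisition_params <- function(carrier_freq = 1.75e6,
                               sound_speed = 1540,
                               insonation_angle = 0,
                               echo_sampling_rate = 6944) {
  stopifnot(is.numeric(carrier_freq), length(carrier_freq) == 1L)
  if (carrier_freq <= 0 || sound_speed <= 0 || echo_sampling_rate <= 0) {
    abort("carrier_freq, sound_speed and echo_sampling_rate must be positive")
  }
  if (insonation_angle < 0 || insonation_angle >= 90) {
    abort("insonation_angle must lie in [0, 90) degrees")
  }
  structure(
    list(
      carrier_freq = carrier_freq,
      sound_speed = sound_speed,
      insonation_angle = insonation_angle,
      echo_sampling_rate = echo_sampling_rate
    ),
    class = "tcd_acquisition"
  )
}

#' Convert a Doppler frequency shift to a flow velocity
#'
#' Applies the Doppler equation `v = df * c / (2 * f_c * cos(alpha))` and
#' reports the result in cm/s. The mapping is linear and sign-preserving, so
#' negative shifts (flow away from the probe) give negative velocities.
#'
#' @param freq_shift Doppler frequency shift(s), Hz. Vectorized.
#' @param acq [acquisition_params()] object.
#' @return Velocity in cm/s, same length as `freq_shift`.
#' @export
freq_to_velocity <- function(freq_shift, acq = acquisition_params()) {
  stopifnot(inherits(acq, "tcd_acquisition"))
  ca <- cos(acq$insonation_angle * pi / 180)
  if (ca <= 0) abort("insonation angle must be below 90 degrees")
  100 * freq_shift * acq$sound_speed / (2 * acq$carrier_freq * ca)
}

#' Inverse of [freq_to_velocity()]
#'
#' @param velocity Velocity in cm/s.
#' @inheritParams freq_to_velocity
#' @return Frequency shift in Hz.
#' @export
velocity_to_freq <- function(velocity, acq = acquisition_params()) {
  stopifnot(inherits(acq, "tcd_acquisition"))
  ca <- cos(acq$insonation_angle * pi / 180)
  if (ca <= 0) abort("insonation angle must be below 90 degrees")
  velocity / 100 * 2 * acq$carrier_freq * ca / acq$sound_speed
}

#' Short-time Fourier transform settings
#'
#' The spectrogram column rate is `1/hop`; with the default hop of 1/217 s the
#' envelope is sampled at 217 Hz. Analysis windows span `window_hops` hops
#' (default 4, i.e. 75% overlap) and are zero-padded to `fft_bins` points,
#' giving a velocity resolution of about 0.30 cm/s at the default acquisition.
#'
#' @param hop Column spacing in seconds.
#' @param window_hops Window length expressed in hops; must be at least 2.
#' @param fft_bins FFT length (zero-padded); must not be shorter than the
#'   window.
#' @param window_shape Taper name; only `"hann"` is implemented.
#' @param dynamic_range Displayed dynamic range in dB used by the
#'   log-compression (see [compute_spectrogram()]).
#' @return An object of class `tcd_stft_config`.
#' @export
stft_config <- function(hop = 1 / 217, window_hops = 4, fft_bins = 1024,
                        window_shape = "hann", dynamic_range = 40) {
  if (hop <= 0) abort("hop must be positive")
  if (window_hops < 2) abort("window_hops must be at least 2")
  window_shape <- match.arg(window_shape, "hann")
  if (dynamic_range <= 0) abort("dynamic_range must be positive")
  structure(
    list(hop = hop, window_hops = window_hops, fft_bins = fft_bins,
         window_shape = window_shape, dynamic_range = dynamic_range),
    class = "tcd_stft_config"
  )
}
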