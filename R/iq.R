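#' Demodulated complex echo signal
#'
#' Container for the in-phase/quadrature (IQ) signal whose instantaneous
#' frequency content encodes scatterer velocities.
#'
#' @param samples Complex vector, uniformly sampled.
#' @param sampling_rate Sampling rate in Hz; must equal
#'   `acquisition$echo_sampling_rate`.
#' @param acquisition [acquisition_params()] object.
#' @return An object of class `tcd_iq`.
#' @export
iq_signal <- function(samples, sampling_rate = acquisition$echo_sampling_rate,
                      acquisition = acquisition_params()) {
  stopifnot(inherits(acquisition, "tcd_acquisition"))
  if (length(samples) == 0L) abort("IQ signal must be non-empty")
  samples <- as.complex(samples)
  if (!isTRUE(all.equal(sampling_rate, acquisition$echo_sampling_rate))) {
    abort("sampling_rate must equal acquisition$echo_sampling_rate")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         acquisition = acquisition),
    class = "tcd_iq"
  )
}

#' @export
print.tcd_iq <- function(x, ...) {
  cat(sprintf("<tcd_iq> %d samples at %.6g Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' High-pass wall filter for the IQ signal
#'
#' Removes low-frequency clutter from slowly moving vessel walls with a
#' second-order Butterworth high-pass, applied zero-phase (forward-backward)
#' to the real and imaginary parts independently. Because of the two passes
#' the effective attenuation at the cutoff is -6 dB (amplitude gain 1/2).
#'
#' @param iq [iq_signal()] object.
#' @param cutoff Cutoff frequency in Hz (default 100); must be below the
#'   Nyquist frequency.
#' @return A filtered `tcd_iq` of the same length.
#' @export
wall_filter <- function(iq, cutoff = 100) {
  stopifnot(inherits(iq, "tcd_iq"))
  fs <- iq$sampling_rate
  if (cutoff >= fs / 2) abort("cutoff must be below the Nyquist frequency")
  flt <- signal::butter(2, cutoff / (fs / 2), type = "high")
  # forward-backward filtering needs enough samples to absorb the transient
  padlen <- max(27L, round(3 * fs / cutoff))
  if (length(iq$samples) <= padlen) {
    abort("IQ signal too short for the wall filter warm-up")
  }
  re <- filter_zerophase(flt, Re(iq$samples), padlen)
  im <- filter_zerophase(flt, Im(iq$samples), padlen)
  iq$samples <- complex(real = re, imaginary = im)
  iq
}
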