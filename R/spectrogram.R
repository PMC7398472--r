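#' Construct a time-velocity spectrogram object
#'
#' Low-level constructor; most users will obtain spectrograms from
#' [compute_spectrogram()], [render_spectrogram()] or [read_spectrogram()].
#' The intensity matrix is stored with velocity bins in rows (ascending, from
#' -v_max upward) and time columns at a uniform hop.
#'
#' @param intensity Numeric matrix in `[0, 1]`, `length(velocities)` rows by
#'   `length(times)` columns.
#' @param times Column times in seconds, strictly increasing, uniform spacing.
#' @param velocities Row velocities in cm/s, strictly increasing, uniform
#'   spacing.
#' @param acquisition [acquisition_params()] object.
#' @return An object of class `tcd_spectrogram`.
#' @export
new_spectrogram <- function(intensity, times, velocities,
                            acquisition = acquisition_params()) {
  stopifnot(is.matrix(intensity))
  if (nrow(intensity) != length(velocities) ||
      ncol(intensity) != length(times)) {
    abort("intensity must be length(velocities) x length(times)")
  }
  rng <- range(intensity)
  if (rng[1] < 0 || rng[2] > 1) abort("intensities must lie in [0, 1]")
  check_uniform_axis(times, "times")
  check_uniform_axis(velocities, "velocities")
  structure(
    list(intensity = intensity, times = times, velocities = velocities,
         acquisition = acquisition),
    class = "tcd_spectrogram"
  )
}

check_uniform_axis <- function(x, name) {
  if (length(x) < 2L) abort(sprintf("axis '%s' needs at least two points", name))
  d <- diff(x)
  if (any(d <= 0)) abort(sprintf("axis '%s' must be strictly increasing", name))
  if (max(d) - min(d) > 1e-6 * max(abs(d))) {
    abort(sprintf("axis '%s' is not uniformly spaced", name))
  }
  invisible(TRUE)
}

#' @export
print.tcd_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<tcd_spectrogram> %d velocity bins x %d columns | %.2f s at %.1f Hz | v in [%.1f, %.1f] cm/s\n",
    nrow(x$intensity), ncol(x$intensity),
    diff(range(x$times)) + diff(x$times[1:2]),
    1 / diff(x$times[1:2]), min(x$velocities), max(x$velocities)))
  invisible(x)
}

spectrogram_hop <- function(sp) diff(sp$times[1:2])

spectrogram_dv <- function(sp) diff(sp$velocities[1:2])

#' Compute a normalized time-velocity spectrogram from an IQ signal
#'
#' Power spectral densities are computed on Hann-tapered windows centered on a
#' uniform hop grid (edges zero-padded), zero-padded to `cfg$fft_bins` points,
#' and mapped to velocity through the Doppler equation. Intensities are
#' log-compressed relative to the global maximum:
#' `intensity = clip(1 + dB / dynamic_range, 0, 1)` with
#' `dB = 10 log10(P / P_max)`, so the brightest pixel is exactly 1 and
#' everything more than `dynamic_range` dB down is 0.
#'
#' With the defaults (hop 1/217 s, 4-hop windows) one second of input yields
#' 217 columns, i.e. the envelope is sampled at 217 Hz.
#'
#' @param iq [iq_signal()] object, long enough for at least one window.
#' @param cfg [stft_config()] object.
#' @return A [new_spectrogram()] object spanning `[-v_max, +v_max)`.
#' @export
compute_spectrogram <- function(iq, cfg = stft_config()) {
  stopifnot(inherits(iq, "tcd_iq"), inherits(cfg, "tcd_stft_config"))
  x <- iq$samples
  fs <- iq$sampling_rate
  hop <- round(fs * cfg$hop)
  if (hop < 1) abort("hop shorter than one sample")
  win <- cfg$window_hops * hop
  nfft <- cfg$fft_bins
  if (nfft < win) abort("fft_bins must be at least the window length")
  n <- length(x)
  if (n < win) abort("IQ signal shorter than one analysis window")

  n_cols <- (n - 1L) %/% hop + 1L
  centers <- (seq_len(n_cols) - 1L) * hop + 1L
  offsets <- seq.int(-(win %/% 2L), win %/% 2L - 1L)
  idx <- outer(offsets, centers, "+")
  frames <- matrix(0 + 0i, nrow = win, ncol = n_cols)
  ok <- idx >= 1L & idx <= n
  frames[ok] <- x[idx[ok]]

  taper <- 0.5 * (1 - cos(2 * pi * (seq_len(win) - 1) / (win - 1)))
  frames <- frames * taper
  padded <- matrix(0 + 0i, nrow = nfft, ncol = n_cols)
  padded[seq_len(win), ] <- frames
  spec <- stats::mvfft(padded)
  pwr <- Mod(spec)^2

  # reorder rows so frequencies run from -fs/2 upward
  half <- nfft %/% 2L
  ord <- c((half + 1L):nfft, 1L:half)
  pwr <- pwr[ord, , drop = FALSE]
  freqs <- (seq_len(nfft) - 1L - half) * fs / nfft

  p_max <- max(pwr)
  if (p_max <= 0) abort("zero-power input: spectrogram normalization undefined")
  intensity <- pmin(pmax(1 + 10 * log10(pwr / p_max) / cfg$dynamic_range, 0), 1)
  dim(intensity) <- dim(pwr)

  new_spectrogram(
    intensity = intensity,
    times = (centers - 1L) / fs,
    velocities = freq_to_velocity(freqs, iq$acquisition),
    acquisition = iq$acquisition
  )
}

#' Select the signal-carrying flow region
#'
#' Compares the summed pixel intensity in the positive velocity band
#' (5 to 125 cm/s) against the mirrored negative band and returns the sign of
#' the richer one (positive flow, e.g. MCA, vs negative flow, e.g. ICA).
#' The band starts at 5 cm/s to exclude the wall-filter stop band. Ties go to
#' the positive side. Sign-crossing (reverse) flow is not detectable.
#'
#' @param sp [new_spectrogram()] object whose velocity axis covers the band.
#' @param band Magnitude band in cm/s, default `c(5, 125)`.
#' @return An object of class `tcd_flow_region` with fields `sign` and
#'   `velocity_band`.
#' @export
select_flow_region <- function(sp, band = c(5, 125)) {
  stopifnot(inherits(sp, "tcd_spectrogram"))
  if (max(sp$velocities) < band[2] * 0.99 ||
      min(sp$velocities) > -band[2] * 0.99) {
    abort("velocity axis does not cover the flow-region band")
  }
  v <- sp$velocities
  pos <- sum(sp$intensity[v >= band[1] & v <= band[2], , drop = FALSE])
  neg <- sum(sp$intensity[v <= -band[1] & v >= -band[2], , drop = FALSE])
  structure(
    list(sign = if (pos >= neg) 1 else -1, velocity_band = band),
    class = "tcd_flow_region"
  )
}

#' Extract a magnitude-oriented velocity band of a spectrogram
#'
#' Returns the sub-image with velocity magnitudes in `[v_lo, v_hi]` on the
#' side given by `sign`, with velocities reported as magnitudes in ascending
#' order (negative-flow spectrograms are flipped; the sign is restored on
#' output by the pipeline).
#'
#' @param sp [new_spectrogram()] object.
#' @param sign `+1` or `-1`, e.g. from [select_flow_region()].
#' @param v_lo,v_hi Magnitude band limits in cm/s.
#' @return A list with `intensity`, `velocities` (magnitudes, ascending),
#'   `times`.
#' @export
spectrogram_band <- function(sp, sign = 1, v_lo = 5, v_hi = Inf) {
  stopifnot(inherits(sp, "tcd_spectrogram"), sign %in% c(-1, 1))
  v <- sp$velocities
  if (sign > 0) {
    keep <- which(v >= v_lo & v <= v_hi)
    list(intensity = sp$intensity[keep, , drop = FALSE],
         velocities = v[keep], times = sp$times)
  } else {
    keep <- which(v <= -v_lo & v >= -v_hi)
    keep <- rev(keep)
    list(intensity = sp$intensity[keep, , drop = FALSE],
         velocities = -v[keep], times = sp$times)
  }
}

#' Plot a spectrogram as a raster image
#'
#' Large spectrograms are decimated to at most `max_px` cells per axis before
#' plotting.
#'
#' @param object [new_spectrogram()] object.
#' @param max_px Maximum cells per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcd_spectrogram <- function(object, max_px = 500, ...) {
  ri <- unique(round(seq(1, nrow(object$intensity),
                         length.out = min(max_px, nrow(object$intensity)))))
  ci <- unique(round(seq(1, ncol(object$intensity),
                         length.out = min(max_px, ncol(object$intensity)))))
  df <- expand.grid(velocity = object$velocities[ri], time = object$times[ci])
  df$intensity <- as.vector(object$intensity[ri, ci])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$velocity,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "velocity (cm/s)", fill = "intensity")
}
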