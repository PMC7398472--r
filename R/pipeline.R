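#' Full estimation pipeline settings
#'
#' Bundles the per-stage configurations and the segmentation of the recording
#' into windows. Each window is processed independently (threshold selection
#' adapts to slow changes in echo intensity); the default window is 60 s, and
#' a final partial window shorter than `min_partial` seconds is merged into
#' the previous one.
#'
#' @param segment_length Window length, seconds (at least 2).
#' @param min_partial Minimal length of a stand-alone final window, seconds.
#' @param stft [stft_config()] object.
#' @param tracer [tracer_config()] object.
#' @param quality [quality_config()] object.
#' @param multipliers Threshold grid multipliers, see [make_threshold_grid()].
#' @param region_band Magnitude band for flow-region selection and Otsu,
#'   cm/s.
#' @param post_cutoff,post_order Low-pass applied to the winning envelope:
#'   Butterworth order and cutoff (Hz), applied zero-phase.
#' @param post_median Length of the final 1D median filter, samples.
#' @return An object of class `tcd_pipeline_config`.
#' @export
pipeline_config <- function(segment_length = 60, min_partial = 10,
                            stft = stft_config(), tracer = tracer_config(),
                            quality = quality_config(),
                            multipliers = c(0.9, 0.95, 1, 1.05, 1.1),
                            region_band = c(5, 125),
                            post_cutoff = 16, post_order = 4,
                            post_median = 3) {
  if (segment_length < 2) abort("segment_length must be at least 2 s")
  structure(
    list(segment_length = segment_length, min_partial = min_partial,
         stft = stft, tracer = tracer, quality = quality,
         multipliers = multipliers, region_band = region_band,
         post_cutoff = post_cutoff, post_order = post_order,
         post_median = post_median),
    class = "tcd_pipeline_config"
  )
}

#' Post-process a raw envelope
#'
#' Smooths the winning raw envelope with a zero-phase Butterworth low-pass
#' (rapid oscillations above ~16 Hz are noise, not physiology) followed by a
#' short 1D median filter that removes isolated single-sample outliers.
#'
#' @param v Raw envelope, cm/s, sampled at `rate`.
#' @param rate Sampling rate, Hz.
#' @param cutoff Low-pass cutoff, Hz.
#' @param order Butterworth order (applied forward-backward).
#' @param median_len Median filter length, samples (odd).
#' @return Smoothed envelope, same length.
#' @export
postprocess_envelope <- function(v, rate = 217, cutoff = 16, order = 4,
                                 median_len = 3) {
  padlen <- max(9L * (order + 1L), round(3 * rate / cutoff))
  if (length(v) <= padlen) {
    abort("envelope shorter than the post-filter warm-up")
  }
  flt <- signal::butter(order, cutoff / (rate / 2), type = "low")
  out <- filter_zerophase(flt, v, padlen)
  as.numeric(runmed(out, median_len, endrule = "median"))
}

#' Estimate the maximal flow velocity envelope of a recording
#'
#' The core feedback loop, per window: select the signal-carrying flow side,
#' compute the Otsu threshold on the flow band, binarize the window at each
#' threshold of the multiplicative grid, despeckle, trace the envelope under
#' the physiological checks, assess each candidate envelope beat-by-beat, and
#' keep the candidate with the smallest artifact index. The winning raw
#' envelope is then low-pass and median filtered and its flow sign restored.
#' A window where every candidate is fully artifactual is still emitted (best
#' available candidate, all samples flagged).
#'
#' @param x A [new_spectrogram()] object or an [iq_signal()] (wall-filtered
#'   and transformed via [compute_spectrogram()] first).
#' @param cfg [pipeline_config()] object.
#' @param wall_cutoff Wall-filter cutoff used when `x` is an IQ signal, Hz.
#' @return An object of class `tcd_envelope`; see [tidy.tcd_envelope()] and
#'   [glance.tcd_envelope()]. The `trace` tibble has columns `time_s`,
#'   `velocity_cm_s` (signed by flow direction), `sqi_pct`, `artifact_flag`,
#'   `segment_id`, `gamma_selected`.
#' @export
estimate_envelope <- function(x, cfg = pipeline_config(), wall_cutoff = 100) {
  if (inherits(x, "tcd_iq")) {
    x <- compute_spectrogram(wall_filter(x, wall_cutoff), cfg$stft)
  }
  stopifnot(inherits(x, "tcd_spectrogram"))
  hop <- spectrogram_hop(x)
  rate <- 1 / hop
  n_cols <- ncol(x$intensity)
  seg_cols <- max(2L, round(cfg$segment_length / hop))
  starts <- seq(1L, n_cols, by = seg_cols)
  ends <- pmin(starts + seg_cols - 1L, n_cols)
  if (length(starts) > 1L &&
      (ends[length(ends)] - starts[length(starts)] + 1L) <
        round(cfg$min_partial / hop)) {
    ends[length(ends) - 1L] <- n_cols
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }

  trace <- vector("list", length(starts))
  segments <- vector("list", length(starts))
  candidates <- vector("list", length(starts))
  beat_rows <- vector("list", length(starts))

  for (s in seq_along(starts)) {
    cols <- starts[s]:ends[s]
    sub <- x
    sub$intensity <- x$intensity[, cols, drop = FALSE]
    sub$times <- x$times[cols]
    res <- process_segment(sub, cfg, rate)

    trace[[s]] <- tibble::tibble(
      time_s = sub$times,
      velocity_cm_s = res$sign * res$velocity,
      sqi_pct = res$sqi,
      artifact_flag = res$artifact,
      segment_id = s,
      gamma_selected = res$gamma_selected
    )
    segments[[s]] <- tibble::tibble(
      segment_id = s, t_start = sub$times[1],
      t_end = sub$times[length(sub$times)], flow_sign = res$sign,
      gamma_otsu = res$gamma_otsu, gamma_selected = res$gamma_selected,
      artifact_index = res$artifact_index, n_beats = res$n_beats
    )
    candidates[[s]] <- dplyr::mutate(res$candidates, segment_id = s,
                                     .before = 1)
    if (nrow(res$beats) > 0L) {
      beat_rows[[s]] <- dplyr::mutate(
        res$beats, onset_s = .data$onset_s + sub$times[1], segment_id = s,
        .before = 1)
    } else {
      beat_rows[[s]] <- dplyr::mutate(res$beats, segment_id = s, .before = 1)
    }
  }

  structure(
    list(trace = dplyr::bind_rows(trace),
         segments = dplyr::bind_rows(segments),
         candidates = dplyr::bind_rows(candidates),
         beats = dplyr::bind_rows(beat_rows),
         config = cfg),
    class = "tcd_envelope"
  )
}

process_segment <- function(sub, cfg, rate) {
  region <- select_flow_region(sub, cfg$region_band)
  otsu_band <- spectrogram_band(sub, region$sign, cfg$region_band[1],
                                cfg$region_band[2])
  gamma_otsu <- suppressWarnings(otsu_threshold(otsu_band))
  grid <- suppressWarnings(make_threshold_grid(gamma_otsu, cfg$multipliers))
  trace_band <- spectrogram_band(sub, region$sign, cfg$region_band[1], Inf)

  reports <- vector("list", length(grid$thresholds))
  raws <- vector("list", length(grid$thresholds))
  for (i in seq_along(grid$thresholds)) {
    gam <- grid$thresholds[i]
    mask <- despeckle(binarize(trace_band, gam))
    raw <- trace_envelope(mask, cfg$tracer)
    onsets <- tryCatch(detect_onsets(raw$velocities, rate, cfg$quality),
                       error = function(e) integer(0))
    reports[[i]] <- assess_quality(raw$velocities, onsets, rate, cfg$quality,
                                   gamma = gam)
    raws[[i]] <- raw
  }
  best <- select_best_candidate(reports, gamma_otsu)
  rep_best <- reports[[best]]
  smooth <- postprocess_envelope(raws[[best]]$velocities, rate,
                                 cfg$post_cutoff, cfg$post_order,
                                 cfg$post_median)
  v_max <- max(trace_band$velocities)
  smooth <- pmin(pmax(smooth, 0), v_max)

  n <- length(smooth)
  sqi <- rep(0, n)
  artifact <- rep(TRUE, n)
  if (rep_best$n_beats > 0L) {
    b <- rep_best$beats
    owner <- findInterval(seq_len(n), b$onset_idx)
    owner <- pmin(pmax(owner, 1L), nrow(b))
    sqi <- b$sqi[owner]
    artifact <- b$artifact[owner]
  }

  list(
    sign = region$sign,
    velocity = smooth,
    sqi = sqi,
    artifact = artifact,
    gamma_otsu = gamma_otsu,
    gamma_selected = rep_best$gamma,
    artifact_index = rep_best$artifact_index,
    n_beats = rep_best$n_beats,
    candidates = tibble::tibble(
      gamma = vapply(reports, function(r) r$gamma, numeric(1)),
      artifact_index = vapply(reports, function(r) r$artifact_index,
                              numeric(1)),
      n_beats = vapply(reports, function(r) r$n_beats, integer(1)),
      selected = seq_along(reports) == best
    ),
    beats = rep_best$beats
  )
}

#' @export
print.tcd_envelope <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<tcd_envelope> %.1f s at %.0f Hz | %d segment(s), %d beats | mean SQI %.1f%% | artifact index %.1f%%\n",
    g$duration_s, g$rate_hz, g$n_segments, g$n_beats, g$mean_sqi,
    g$artifact_index))
  invisible(x)
}

#' Per-beat tidy summary of an estimated envelope
#'
#' @param x [estimate_envelope()] result.
#' @param ... Unused.
#' @return A tibble with one row per detected beat (onset, duration, screen
#'   outcome, NMSE, SQI, artifact flag, owning segment).
#' @export
tidy.tcd_envelope <- function(x, ...) x$beats

#' One-row summary of an estimated envelope
#'
#' @param x [estimate_envelope()] result.
#' @param ... Unused.
#' @return A one-row tibble: duration, rate, segment and beat counts, mean
#'   SQI over beats, percentage of flagged beats.
#' @export
glance.tcd_envelope <- function(x, ...) {
  dt <- diff(x$trace$time_s[1:2])
  tibble::tibble(
    duration_s = nrow(x$trace) * dt,
    rate_hz = 1 / dt,
    n_segments = nrow(x$segments),
    n_beats = nrow(x$beats),
    mean_sqi = if (nrow(x$beats)) mean(x$beats$sqi) else NA_real_,
    artifact_index = if (nrow(x$beats)) {
      100 * mean(x$beats$artifact)
    } else 100
  )
}

#' Plot an estimated envelope colored by beat signal quality
#'
#' @param object [estimate_envelope()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcd_envelope <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$time_s, .data$velocity_cm_s,
                               color = .data$sqi_pct)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_color_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = "time (s)", y = "maximal flow velocity (cm/s)",
                  color = "SQI (%)")
}
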