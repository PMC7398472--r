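#' Beat screening and signal-quality settings
#'
#' Thresholds of the four physiological beat screens and of the template
#' matching stage. A beat passes the screens iff its systolic maximum exceeds
#' `min_systolic`, its velocity range (pulsatility) exceeds `min_pulse`, its
#' duration lies in `(min_duration, max_duration)` (heart rate between 30 and
#' 240 bpm) and its duration lies within `rel_duration_band` times the segment
#' median duration (rejecting split or merged beats). Template matching
#' evaluates the normalized MSE on the first `template_fraction` of the
#' template duration (the diastolic tail varies with heart rate); beats with
#' NMSE above `nmse_flag` are artifacts.
#'
#' @param min_systolic Minimal per-beat maximum, cm/s.
#' @param min_pulse Minimal max-min velocity difference, cm/s.
#' @param min_duration,max_duration Absolute beat duration band, s.
#' @param rel_duration_band Relative duration band, multiples of the median.
#' @param template_fraction Fraction of the template entering the NMSE.
#' @param nmse_flag NMSE above which a beat is flagged as artifact.
#' @param abp_peak_target Rescaling level for onset detection: the envelope is
#'   scaled so its mean per-beat peak is near this value, matching the
#'   amplitude range the arterial-pulse onset detector expects (mmHg-like).
#' @return An object of class `tcd_quality_config`.
#' @export
quality_config <- function(min_systolic = 30, min_pulse = 20,
                           min_duration = 0.25, max_duration = 2,
                           rel_duration_band = c(0.5, 2),
                           template_fraction = 0.75, nmse_flag = 0.30,
                           abp_peak_target = 140) {
  stopifnot(min_systolic > 0, min_pulse > 0, min_duration > 0,
            max_duration > min_duration, length(rel_duration_band) == 2,
            nmse_flag > 0, abp_peak_target > 0)
  if (template_fraction <= 0 || template_fraction > 1) {
    abort("template_fraction must lie in (0, 1]")
  }
  structure(
    list(min_systolic = min_systolic, min_pulse = min_pulse,
         min_duration = min_duration, max_duration = max_duration,
         rel_duration_band = rel_duration_band,
         template_fraction = template_fraction, nmse_flag = nmse_flag,
         abp_peak_target = abp_peak_target),
    class = "tcd_quality_config"
  )
}

#' Detect beat onsets in a flow-velocity envelope
#'
#' A slope-sum-function (SSF) onset detector in the style of arterial-pulse
#' onset detectors: the envelope is first linearly rescaled so that its mean
#' per-beat peak is near `cfg$abp_peak_target` (making the detector scale
#' invariant), then the SSF - a 128 ms running sum of the positive slope - is
#' thresholded adaptively (half the median of the most recent SSF peaks) with
#' a 250 ms refractory period. Each detected surge is backtracked to the
#' envelope minimum immediately preceding it, which marks the onset.
#'
#' @param env Numeric envelope, cm/s, sampled at `rate`.
#' @param rate Sampling rate, Hz (default 217).
#' @param cfg [quality_config()] object.
#' @return Strictly increasing integer onset indices (possibly empty for
#'   pulseless input).
#' @export
detect_onsets <- function(env, rate = 217, cfg = quality_config()) {
  n <- length(env)
  if (n < 2 * rate) abort("envelope shorter than 2 s: cannot detect onsets")
  if (max(env) - min(env) < 1e-9) return(integer(0))

  # provisional peak pass for the amplitude rescaling
  pk <- local_maxima(env, min_dist = round(0.3 * rate))
  pk <- pk[env[pk] > mean(env)]
  if (length(pk) == 0L) return(integer(0))
  z <- env * (cfg$abp_peak_target / mean(env[pk]))

  w <- max(2L, round(0.128 * rate))
  d <- pmax(diff(z), 0)
  ssf <- c(0, cumsum(d))
  ssf <- ssf[pmin(seq_len(n), n)] - ssf[pmax(seq_len(n) - w, 1L)]

  refractory <- round(0.25 * rate)
  search_fwd <- round(0.30 * rate)
  search_back <- round(0.35 * rate)
  recent <- max(ssf[seq_len(min(n, 2L * round(rate)))])
  theta <- 0.5 * recent
  recent <- rep(recent, 1L)

  onsets <- integer(0)
  k <- 2L
  last_onset <- -Inf
  while (k <= n) {
    if (ssf[k] >= theta && ssf[k - 1L] < theta) {
      hi <- min(n, k + search_fwd)
      p <- (k - 1L) + which.max(ssf[k:hi])
      lo <- max(1L, p - search_back)
      w <- z[lo:p]
      # last point of the minimum plateau = foot of the upstroke
      onset <- (lo - 1L) + max(which(w <= min(w) + 1e-9))
      if (onset - last_onset >= refractory) {
        onsets <- c(onsets, onset)
        last_onset <- onset
        recent <- tail(c(recent, ssf[p]), 8L)
        theta <- 0.5 * median(recent)
      }
      k <- p + refractory
    } else {
      k <- k + 1L
    }
  }
  unique(onsets)
}

local_maxima <- function(x, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] >= x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  if (length(cand) <= 1L || min_dist <= 1L) return(cand)
  keep <- integer(0)
  for (i in cand[order(-x[cand])]) {
    if (all(abs(i - keep) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Split an envelope into beats at the detected onsets
#'
#' Beats span consecutive onsets; samples after the last onset do not form a
#' beat.
#'
#' @param env Numeric envelope, cm/s.
#' @param onsets Onset indices from [detect_onsets()].
#' @param rate Sampling rate, Hz.
#' @return A tibble with one row per beat: `beat`, `onset_idx`, `end_idx`,
#'   `onset_s`, `duration_s`, and list-column `samples`.
#' @export
beats_from_onsets <- function(env, onsets, rate = 217) {
  if (length(onsets) < 2L) {
    return(tibble::tibble(beat = integer(0), onset_idx = integer(0),
                          end_idx = integer(0), onset_s = numeric(0),
                          duration_s = numeric(0), samples = list()))
  }
  start <- onsets[-length(onsets)]
  end <- onsets[-1L] - 1L
  tibble::tibble(
    beat = seq_along(start),
    onset_idx = start,
    end_idx = end,
    onset_s = (start - 1L) / rate,
    duration_s = (end - start + 1L) / rate,
    samples = purrr::map2(start, end, function(a, b) env[a:b])
  )
}

#' Apply the four physiological beat screens
#'
#' See [quality_config()] for the conditions. The median beat duration used by
#' the relative-duration screen is computed over all beats of the segment.
#' Reason codes: 1 low systolic maximum, 2 low pulsatility, 3 duration outside
#' the absolute band, 4 duration outside the relative band.
#'
#' @param beats Tibble from [beats_from_onsets()].
#' @param cfg [quality_config()] object.
#' @return The beats tibble with logical `passed` and character `reasons`
#'   (comma-separated codes, empty when passed).
#' @export
screen_beats <- function(beats, cfg = quality_config()) {
  if (nrow(beats) == 0L) abort("no beats to screen")
  med_dur <- median(beats$duration_s)
  res <- purrr::map2(beats$samples, beats$duration_s, function(s, d) {
    fail <- integer(0)
    if (max(s) <= cfg$min_systolic) fail <- c(fail, 1L)
    if (max(s) - min(s) <= cfg$min_pulse) fail <- c(fail, 2L)
    if (d <= cfg$min_duration || d >= cfg$max_duration) fail <- c(fail, 3L)
    if (d <= cfg$rel_duration_band[1] * med_dur ||
        d >= cfg$rel_duration_band[2] * med_dur) fail <- c(fail, 4L)
    fail
  })
  beats$passed <- lengths(res) == 0L
  beats$reasons <- purrr::map_chr(res, paste, collapse = ",")
  beats
}

#' Median beat template of the valid beats
#'
#' Valid beats are zero-padded to the longest one, the pointwise median is
#' taken, and the template is truncated to the median valid-beat duration
#' (rounded down for even counts).
#'
#' @param valid_beats List of numeric beat vectors (screen-passing beats).
#' @return Numeric template vector.
#' @export
build_template <- function(valid_beats) {
  if (length(valid_beats) == 0L) {
    abort("no valid beats: segment unusable for template matching")
  }
  lens <- lengths(valid_beats)
  l_max <- max(lens)
  mat <- vapply(valid_beats, function(b) c(b, rep(0, l_max - length(b))),
                numeric(l_max))
  tpl <- apply(matrix(mat, nrow = l_max), 1, median)
  tpl[seq_len(floor(median(lens)))]
}

#' Normalized mean squared error between a beat and the template
#'
#' Computed on the first `fraction` of the template duration only, so that
#' heart-rate variability in the diastolic tail does not penalize the beat.
#' The beat is zero-padded or truncated to that window, and the MSE is
#' normalized by the template's mean square over the same window.
#'
#' @param beat Numeric beat vector.
#' @param template Numeric template vector from [build_template()].
#' @param fraction Evaluated fraction of the template duration.
#' @return The NMSE (dimensionless, 0 for a perfect match).
#' @export
normalized_mse <- function(beat, template, fraction = 0.75) {
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  wlen <- floor(fraction * length(template))
  if (wlen < 1L) abort("template too short for the evaluation window")
  t_w <- template[seq_len(wlen)]
  if (all(t_w == 0)) abort("all-zero template window: NMSE undefined")
  b_w <- c(beat, rep(0, max(0, wlen - length(beat))))[seq_len(wlen)]
  mean((b_w - t_w)^2) / mean(t_w^2)
}

#' Beat-by-beat quality assessment of one candidate envelope
#'
#' Runs the four screens, builds the median template from the screen-passing
#' beats, and computes each passing beat's NMSE against the template. A beat
#' is flagged as artifact if it fails a screen or its NMSE exceeds
#' `cfg$nmse_flag`. The artifact index is the percentage of flagged beats;
#' the per-beat signal quality index is `100 * max(0, 1 - NMSE)` (0 for
#' screen-failed beats). A segment with no valid beats gets artifact index
#' 100.
#'
#' @param env Numeric candidate envelope, cm/s.
#' @param onsets Onset indices from [detect_onsets()].
#' @param rate Sampling rate, Hz.
#' @param cfg [quality_config()] object.
#' @param gamma Segmentation threshold that produced `env` (bookkeeping).
#' @return An object of class `tcd_quality_report`: list with `beats` tibble
#'   (`onset_idx`, `end_idx`, `onset_s`, `duration_s`, `passed`, `reasons`,
#'   `nmse`, `sqi`, `artifact`), `artifact_index` (percent), `n_beats`,
#'   `gamma`, `template`.
#' @export
assess_quality <- function(env, onsets, rate = 217, cfg = quality_config(),
                           gamma = NA_real_) {
  beats <- beats_from_onsets(env, onsets, rate)
  if (nrow(beats) == 0L) {
    return(structure(
      list(beats = dplyr::mutate(beats, passed = logical(0),
                                 reasons = character(0), nmse = numeric(0),
                                 sqi = numeric(0), artifact = logical(0)),
           artifact_index = 100, n_beats = 0L, gamma = gamma,
           template = numeric(0)),
      class = "tcd_quality_report"
    ))
  }
  beats <- screen_beats(beats, cfg)
  beats$nmse <- NA_real_
  beats$sqi <- 0
  beats$artifact <- !beats$passed
  valid <- which(beats$passed)
  template <- numeric(0)
  if (length(valid) > 0L) {
    template <- build_template(beats$samples[valid])
    nmse <- vapply(beats$samples[valid], normalized_mse, numeric(1),
                   template = template, fraction = cfg$template_fraction)
    beats$nmse[valid] <- nmse
    beats$sqi[valid] <- 100 * pmax(0, 1 - nmse)
    beats$artifact[valid] <- nmse > cfg$nmse_flag
  }
  structure(
    list(beats = dplyr::select(beats, -"samples"),
         artifact_index = 100 * sum(beats$artifact) / nrow(beats),
         n_beats = nrow(beats), gamma = gamma, template = template),
    class = "tcd_quality_report"
  )
}

#' @export
print.tcd_quality_report <- function(x, ...) {
  cat(sprintf("<tcd_quality_report> %d beats | artifact index %.1f%% | gamma %s\n",
              x$n_beats, x$artifact_index,
              ifelse(is.na(x$gamma), "NA", format(x$gamma, digits = 4))))
  invisible(x)
}

#' Select the candidate envelope with the smallest artifact index
#'
#' Ties are broken toward the threshold closest to the Otsu threshold, then
#' toward the smaller threshold.
#'
#' @param reports List of [assess_quality()] reports, one per candidate
#'   threshold (each with its `gamma` set).
#' @param gamma_otsu The Otsu threshold of the segment.
#' @return The index of the winning report within `reports`.
#' @export
select_best_candidate <- function(reports, gamma_otsu) {
  if (length(reports) == 0L) abort("no candidate reports")
  ai <- vapply(reports, function(r) r$artifact_index, numeric(1))
  gam <- vapply(reports, function(r) r$gamma, numeric(1))
  ord <- order(ai, abs(gam - gamma_otsu), gam)
  ord[1L]
}
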