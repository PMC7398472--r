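#' Align the sign of estimated and reference envelopes
#'
#' Flow away from the probe (e.g. ICA) gives negative velocities; so that
#' positive- and negative-flow recordings can be compared on one scale, both
#' series are negated when the reference is predominantly negative.
#' A genuinely mixed-sign reference (reverse flow) is not supported.
#'
#' @param v_algo Estimated envelope, cm/s.
#' @param v_man Reference (e.g. manually traced) envelope, same length.
#' @return A list with sign-aligned `v_algo` and `v_man`.
#' @export
align_signs <- function(v_algo, v_man) {
  if (length(v_algo) != length(v_man)) abort("envelopes differ in length")
  m <- mean(v_man)
  ma <- mean(abs(v_man))
  if (ma > 0 && abs(m) < 0.5 * ma) {
    abort("mixed-sign reference: reverse flow is not supported")
  }
  if (m < 0) list(v_algo = -v_algo, v_man = -v_man)
  else list(v_algo = v_algo, v_man = v_man)
}

#' Whole-waveform agreement metrics
#'
#' For the error signal `e = v_algo - v_man`: the bias `m_e = mean(e)`, the
#' error standard deviation `sigma_e` (population convention, divide by N),
#' and the relative error `r_e = sum(e) / sum(v_man)`.
#'
#' @inheritParams align_signs
#' @return A list with `n`, `m_e`, `sigma_e`, `r_e` (all cm/s except the
#'   dimensionless `r_e`).
#' @export
waveform_errors <- function(v_algo, v_man) {
  if (length(v_algo) != length(v_man)) abort("envelopes differ in length")
  n <- length(v_man)
  if (n < 1L) abort("need at least one sample")
  e <- v_algo - v_man
  m_e <- mean(e)
  sigma_e <- sqrt(mean((e - m_e)^2))
  denom <- sum(v_man)
  if (denom == 0) abort("reference sums to zero: relative error undefined")
  list(n = n, m_e = m_e, sigma_e = sigma_e, r_e = sum(e) / denom)
}

#' Peak-systolic agreement metrics
#'
#' For paired per-beat peak velocities: bias, population standard deviation
#' and relative error of the peak differences, plus the Bland-Altman pairs
#' (per-beat mean and difference).
#'
#' @param peaks_algo,peaks_man Paired per-beat peak velocities, cm/s.
#' @return A list with `n_beats`, `m_dpeak`, `sigma_dpeak`, `r_dpeak`, and a
#'   tibble `bland_altman` with columns `mean` and `diff`.
#' @export
peak_errors <- function(peaks_algo, peaks_man) {
  if (length(peaks_algo) != length(peaks_man)) {
    abort("peak vectors differ in length")
  }
  if (length(peaks_man) < 1L) abort("need at least one beat")
  d <- peaks_algo - peaks_man
  m <- mean(d)
  denom <- sum(peaks_man)
  if (denom == 0) abort("reference peaks sum to zero: relative error undefined")
  list(
    n_beats = length(d),
    m_dpeak = m,
    sigma_dpeak = sqrt(mean((d - m)^2)),
    r_dpeak = sum(d) / denom,
    bland_altman = tibble::tibble(mean = (peaks_algo + peaks_man) / 2,
                                  diff = d)
  )
}

#' Evaluate an estimated envelope against a reference trace
#'
#' Sign-aligns the two series, computes the whole-waveform metrics, detects
#' beats in both independently, pairs beats whose onsets lie within
#' `match_window` of each other (nearest-onset, one-to-one, unmatched beats
#' are excluded and counted), and computes the peak-systolic metrics on the
#' paired per-beat maxima.
#'
#' @param v_algo Estimated envelope, cm/s, sampled at `rate`.
#' @param v_man Reference envelope, same length and rate.
#' @param rate Sampling rate, Hz.
#' @param match_window Maximal onset distance for pairing, seconds.
#' @param cfg [quality_config()] used by the onset detector.
#' @return An object of class `tcd_eval`: the [waveform_errors()] and
#'   [peak_errors()] fields plus `n_unmatched_algo`, `n_unmatched_man`.
#' @export
evaluate_envelope <- function(v_algo, v_man, rate = 217, match_window = 0.3,
                              cfg = quality_config()) {
  al <- align_signs(v_algo, v_man)
  wf <- waveform_errors(al$v_algo, al$v_man)

  on_a <- detect_onsets(al$v_algo, rate, cfg)
  on_m <- detect_onsets(al$v_man, rate, cfg)
  beats_a <- beats_from_onsets(al$v_algo, on_a, rate)
  beats_m <- beats_from_onsets(al$v_man, on_m, rate)
  pairs <- pair_beats(beats_a$onset_s, beats_m$onset_s, match_window)

  pk <- NULL
  if (nrow(pairs) > 0L) {
    pa <- vapply(beats_a$samples[pairs$a], max, numeric(1))
    pm <- vapply(beats_m$samples[pairs$m], max, numeric(1))
    pk <- peak_errors(pa, pm)
  }
  structure(
    c(wf,
      pk %||% list(n_beats = 0L, m_dpeak = NA_real_, sigma_dpeak = NA_real_,
                   r_dpeak = NA_real_,
                   bland_altman = tibble::tibble(mean = numeric(0),
                                                 diff = numeric(0))),
      list(n_unmatched_algo = nrow(beats_a) - nrow(pairs),
           n_unmatched_man = nrow(beats_m) - nrow(pairs))),
    class = "tcd_eval"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Greedy one-to-one nearest-onset pairing within a window.
pair_beats <- function(onsets_a, onsets_m, window) {
  if (length(onsets_a) == 0L || length(onsets_m) == 0L) {
    return(tibble::tibble(a = integer(0), m = integer(0)))
  }
  d <- abs(outer(onsets_a, onsets_m, "-"))
  d[d > window] <- NA
  pairs <- list()
  while (any(is.finite(d))) {
    i <- arrayInd(which.min(d), dim(d))
    pairs[[length(pairs) + 1L]] <- c(a = i[1], m = i[2])
    d[i[1], ] <- NA
    d[, i[2]] <- NA
  }
  if (length(pairs) == 0L) {
    return(tibble::tibble(a = integer(0), m = integer(0)))
  }
  out <- do.call(rbind, pairs)
  out <- out[order(out[, "a"]), , drop = FALSE]
  tibble::tibble(a = out[, "a"], m = out[, "m"])
}

#' @export
print.tcd_eval <- function(x, ...) {
  cat(sprintf(
    "<tcd_eval> N = %d samples: bias %.2f cm/s, sd %.2f cm/s, rel %.2f%%\n",
    x$n, x$m_e, x$sigma_e, 100 * x$r_e))
  cat(sprintf(
    "           %d paired beats: peak bias %.2f cm/s, sd %.2f cm/s, rel %.2f%%\n",
    x$n_beats, x$m_dpeak, x$sigma_dpeak, 100 * x$r_dpeak))
  invisible(x)
}

#' Long-format agreement metrics
#'
#' @param x [evaluate_envelope()] result.
#' @param ... Unused.
#' @return A tibble with columns `metric` and `value`.
#' @export
tidy.tcd_eval <- function(x, ...) {
  tibble::tibble(
    metric = c("n", "m_e", "sigma_e", "r_e", "n_beats", "m_dpeak",
               "sigma_dpeak", "r_dpeak", "n_unmatched_algo",
               "n_unmatched_man"),
    value = c(x$n, x$m_e, x$sigma_e, x$r_e, x$n_beats, x$m_dpeak,
              x$sigma_dpeak, x$r_dpeak, x$n_unmatched_algo,
              x$n_unmatched_man)
  )
}

#' One-row agreement summary
#'
#' @param x [evaluate_envelope()] result.
#' @param ... Unused.
#' @return A one-row tibble of all agreement metrics.
#' @export
glance.tcd_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n, m_e = x$m_e, sigma_e = x$sigma_e, r_e = x$r_e,
    n_beats = x$n_beats, m_dpeak = x$m_dpeak, sigma_dpeak = x$sigma_dpeak,
    r_dpeak = x$r_dpeak, n_unmatched_algo = x$n_unmatched_algo,
    n_unmatched_man = x$n_unmatched_man
  )
}

#' Bland-Altman plot of paired peak-systolic velocities
#'
#' @param object [evaluate_envelope()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcd_eval <- function(object, ...) {
  ba <- object$bland_altman
  ggplot2::ggplot(ba, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = mean(ba$diff), linetype = 2) +
    ggplot2::geom_hline(yintercept = mean(ba$diff) +
                          c(-1.96, 1.96) * stats::sd(ba$diff),
                        linetype = 3) +
    ggplot2::labs(x = "mean peak velocity (cm/s)",
                  y = "difference (cm/s)")
}
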