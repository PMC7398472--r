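#' Modified threshold crossing method settings
#'
#' The MTCM is the classical fixed-threshold comparator: per spectrogram
#' column a group of `group_size` adjacent velocity bins slides from the
#' high-velocity (noise) end toward zero, and the first group in which at
#' least `min_exceed` bins exceed the preset intensity threshold sets the
#' envelope to the group's highest-velocity bin. The threshold is held
#' constant over a whole segment and, unlike the adaptive pipeline, must be
#' picked by the user to match the spectrogram's SNR.
#'
#' @param group_size Bins per sliding group.
#' @param min_exceed Bins that must exceed the threshold.
#' @param threshold Preset intensity threshold in `[0, 1]`.
#' @param noise_rows Top-velocity rows used by [mtcm_noise_floor()].
#' @return An object of class `tcd_mtcm_config`.
#' @export
mtcm_config <- function(group_size = 10, min_exceed = 5, threshold = 0.6,
                        noise_rows = 20) {
  stopifnot(group_size >= 1, min_exceed >= 1, noise_rows >= 1)
  if (min_exceed > group_size) abort("min_exceed must not exceed group_size")
  if (threshold < 0 || threshold > 1) abort("threshold must lie in [0, 1]")
  structure(
    list(group_size = group_size, min_exceed = min_exceed,
         threshold = threshold, noise_rows = noise_rows),
    class = "tcd_mtcm_config"
  )
}

#' Noise floor estimate for the MTCM
#'
#' Mean intensity of the top `noise_rows` velocity rows of the magnitude
#' band, which lie above any physiological flow and therefore sample the
#' noise floor. Useful as a starting point when picking the MTCM threshold.
#'
#' @param band [spectrogram_band()] list.
#' @param noise_rows Number of top rows.
#' @return Mean noise intensity.
#' @export
mtcm_noise_floor <- function(band, noise_rows = 20) {
  n <- nrow(band$intensity)
  rows <- seq.int(max(1L, n - noise_rows + 1L), n)
  mean(band$intensity[rows, , drop = FALSE])
}

#' MTCM baseline envelope
#'
#' @param sp [new_spectrogram()] object or [spectrogram_band()] list. A full
#'   spectrogram is first reduced to its signal-carrying magnitude band via
#'   [select_flow_region()].
#' @param cfg [mtcm_config()] object.
#' @return An object of class `tcd_raw_envelope` with magnitudes in cm/s
#'   (columns where no group qualifies get 0).
#' @export
mtcm_envelope <- function(sp, cfg = mtcm_config()) {
  if (inherits(sp, "tcd_spectrogram")) {
    region <- select_flow_region(sp)
    band <- spectrogram_band(sp, region$sign, region$velocity_band[1], Inf)
  } else {
    band <- sp
  }
  g <- cfg$group_size
  if (nrow(band$intensity) < g) {
    abort("flow band has fewer rows than the MTCM group size")
  }
  above <- band$intensity > cfg$threshold
  cs <- rbind(0, apply(above, 2, cumsum))
  n_rows <- nrow(band$intensity)
  tops <- seq.int(g, n_rows)            # group top row indices (ascending)
  counts <- cs[tops + 1L, , drop = FALSE] - cs[tops - g + 1L, , drop = FALSE]
  ok <- counts >= cfg$min_exceed
  env <- apply(ok, 2, function(z) {
    hit <- which(z)
    if (length(hit) == 0L) return(NA_integer_)
    tops[max(hit)]                      # first group from the noise end
  })
  v <- ifelse(is.na(env), 0, band$velocities[ifelse(is.na(env), 1L, env)])
  structure(
    list(velocities = as.numeric(v), held = rep(FALSE, length(v)),
         override = rep(FALSE, length(v)), times = band$times),
    class = "tcd_raw_envelope"
  )
}
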