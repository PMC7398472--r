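#' Otsu threshold of an intensity sample
#'
#' Computes the binary segmentation threshold that minimizes the within-class
#' intensity variance over a fixed 256-bin histogram of `[0, 1]`, by exhaustive
#' search over all bin edges (the classical Otsu criterion, equivalent to
#' two-class k-means on scalar data). Ties are broken toward the smallest
#' threshold. In the envelope pipeline this is evaluated on the selected flow
#' band only, where signal and noise classes are roughly balanced.
#'
#' @param x Numeric vector of intensities in `[0, 1]`, or an object with an
#'   `intensity` field ([new_spectrogram()] or a [spectrogram_band()] list).
#' @param n_bins Histogram bin count (default 256, 8-bit convention).
#' @return The threshold (a bin edge `k / n_bins`). A constant input is
#'   degenerate: its value is returned with a warning and attribute
#'   `degenerate = TRUE`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  if (is.list(x) && !is.null(x$intensity)) x <- x$intensity
  x <- as.vector(x)
  if (length(x) == 0L) abort("empty intensity sample")
  if (any(x < 0 | x > 1)) abort("intensities must lie in [0, 1]")
  if (max(x) - min(x) < 1e-12) {
    warn("constant-intensity region: Otsu threshold is degenerate")
    return(structure(x[1], degenerate = TRUE))
  }
  bins <- pmin(floor(x * n_bins), n_bins - 1)           # 0-based bin index
  cnt <- tabulate(bins + 1L, n_bins)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  n <- length(x)

  c_n <- cumsum(cnt)
  c_m <- cumsum(cnt * centers)
  c_s <- cumsum(cnt * centers^2)
  w0 <- c_n[-n_bins]
  w1 <- n - w0
  s0 <- c_s[-n_bins] - c_m[-n_bins]^2 / ifelse(w0 > 0, w0, NA)
  s1 <- (c_s[n_bins] - c_s[-n_bins]) -
    (c_m[n_bins] - c_m[-n_bins])^2 / ifelse(w1 > 0, w1, NA)
  wcv <- (s0 + s1) / n
  wcv[w0 == 0 | w1 == 0] <- Inf
  if (all(!is.finite(wcv))) {
    warn("all intensity mass in one histogram bin: Otsu threshold is degenerate")
    return(structure(mean(x), degenerate = TRUE))
  }
  k <- which.min(wcv)                                   # smallest index on ties
  k / n_bins
}

#' Multiplicative grid of candidate segmentation thresholds
#'
#' The Otsu threshold alone tends to give overly flat envelopes, but small
#' adaptations of it often segment well, so the pipeline searches a grid of
#' multiples of the Otsu threshold (default 0.9 to 1.1) and lets the signal
#' quality loop pick the winner.
#'
#' @param otsu Otsu threshold in `[0, 1]`.
#' @param multipliers Grid multipliers.
#' @return An object of class `tcd_threshold_grid` with fields
#'   `otsu_threshold`, `multipliers`, `thresholds` (products clipped to at
#'   most 1, sorted ascending) and `degenerate` (`TRUE` when `otsu` is 0).
#' @export
make_threshold_grid <- function(otsu, multipliers = c(0.9, 0.95, 1, 1.05, 1.1)) {
  otsu <- as.numeric(otsu)
  if (otsu < 0 || otsu > 1) abort("otsu threshold must lie in [0, 1]")
  degenerate <- otsu == 0
  if (degenerate) warn("zero Otsu threshold: the threshold grid is degenerate")
  structure(
    list(otsu_threshold = otsu, multipliers = multipliers,
         thresholds = sort(pmin(otsu * multipliers, 1)),
         degenerate = degenerate),
    class = "tcd_threshold_grid"
  )
}

#' Binarize a spectrogram at an intensity threshold
#'
#' A pixel is signal (white) iff its intensity is `>=` the threshold, so
#' threshold 0 marks everything as signal and masks shrink monotonically as
#' the threshold grows.
#'
#' @param sp [new_spectrogram()] object or [spectrogram_band()] list.
#' @param threshold Intensity threshold in `[0, 1]` (values above 1 give an
#'   all-false mask).
#' @return An object of class `tcd_mask` with logical matrix `mask` (same
#'   shape as the source), `threshold_used`, and the source axes.
#' @export
binarize <- function(sp, threshold) {
  if (threshold < 0) abort("threshold must be non-negative")
  structure(
    list(mask = sp$intensity >= threshold, threshold_used = threshold,
         times = sp$times, velocities = sp$velocities),
    class = "tcd_mask"
  )
}

#' Remove speckle from a binary mask with a 2D median filter
#'
#' The kernel is specified physically (0.03 s by 5 cm/s, matched to the
#' typical speckle shape) and converted to odd pixel counts using the mask's
#' axis spacings, rounding to the nearest odd integer so the median is
#' centered. Boundaries are handled by edge replication. On a binary image the
#' median is a majority vote, computed here with an integral image.
#'
#' @param mask [binarize()] output.
#' @param kernel_time Kernel length along time, seconds.
#' @param kernel_velocity Kernel length along velocity, cm/s.
#' @return A despeckled `tcd_mask` of the same shape.
#' @export
despeckle <- function(mask, kernel_time = 0.03, kernel_velocity = 5) {
  stopifnot(inherits(mask, "tcd_mask"))
  dt <- diff(mask$times[1:2])
  dv <- diff(mask$velocities[1:2])
  kx <- nearest_odd(kernel_time / dt)
  ky <- nearest_odd(kernel_velocity / dv)
  m <- mask$mask
  if (ky > nrow(m) || kx > ncol(m)) {
    abort(sprintf("despeckle kernel (%d x %d) larger than mask (%d x %d)",
                  ky, kx, nrow(m), ncol(m)))
  }
  mask$mask <- binary_median_2d(m, ky, kx)
  mask
}

nearest_odd <- function(x) max(1L, as.integer(2 * round((x - 1) / 2) + 1))

# Majority filter on a logical matrix with edge replication, via an integral
# image; ky/kx must be odd.
binary_median_2d <- function(m, ky, kx) {
  nr <- nrow(m); nc <- ncol(m)
  ry <- (ky - 1L) %/% 2L; rx <- (kx - 1L) %/% 2L
  pad <- m[c(rep(1L, ry), seq_len(nr), rep(nr, ry)),
           c(rep(1L, rx), seq_len(nc), rep(nc, rx)), drop = FALSE]
  s <- apply(pad, 2, cumsum)
  s <- rbind(0, s)
  s <- t(apply(s, 1, cumsum))
  s <- cbind(0, s)
  ri <- seq_len(nr); ci <- seq_len(nc)
  cnt <- s[ri + ky, ci + kx, drop = FALSE] -
    s[ri, ci + kx, drop = FALSE] -
    s[ri + ky, ci, drop = FALSE] +
    s[ri, ci, drop = FALSE]
  cnt * 2 > ky * kx
}
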