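# Independent oracles and shared fixtures. Oracles are deliberately written
# as plain brute-force code, independent of the package's implementation.

# Brute-force Otsu: scan every histogram split point, computing the weighted
# within-class variance directly from the binned sample.
oracle_otsu <- function(x, n_bins = 256) {
  bins <- pmin(floor(x * n_bins), n_bins - 1)
  centers <- (bins + 0.5) / n_bins
  n <- length(x)
  pop_var <- function(v) if (length(v) == 0) NA else mean((v - mean(v))^2)
  best <- Inf
  best_k <- NA
  for (k in 1:(n_bins - 1)) {
    lo <- centers[centers < k / n_bins]
    hi <- centers[centers >= k / n_bins]
    if (length(lo) == 0 || length(hi) == 0) next
    wcv <- (length(lo) * pop_var(lo) + length(hi) * pop_var(hi)) / n
    if (wcv < best) {
      best <- wcv
      best_k <- k
    }
  }
  best_k / n_bins
}

# Digital second-order Butterworth high-pass amplitude response (bilinear
# transform with prewarped cutoff), squared for forward-backward filtering.
oracle_hp2_filtfilt_gain <- function(f, cutoff, fs) {
  1 / (1 + (tan(pi * cutoff / fs) / tan(pi * f / fs))^4)
}

# Top-edge scan: highest row whose intensity exceeds half the signal plateau.
oracle_top_edge <- function(sp, level = 0.75) {
  pos <- sp$velocities > 0
  v <- sp$velocities[pos]
  apply(sp$intensity[pos, , drop = FALSE], 2, function(col) {
    hit <- which(col >= level)
    if (length(hit) == 0) NA_real_ else v[max(hit)]
  })
}

# Direct simulation of the MTCM group rule on a single column.
oracle_mtcm_column <- function(intens, velocities, threshold, group = 10,
                               exceed = 5) {
  n <- length(intens)
  for (top in seq(n, group, by = -1)) {
    grp <- (top - group + 1):top
    if (sum(intens[grp] > threshold) >= exceed) return(velocities[top])
  }
  0
}

# Build a magnitude-oriented tcd_mask from a vector of edge row indices:
# column j is white for all rows <= edge_rows[j] (0 = all black).
edge_mask <- function(edge_rows, n_rows = 200, dv = 0.3, v0 = 5,
                      extra_white = NULL) {
  m <- matrix(FALSE, n_rows, length(edge_rows))
  for (j in seq_along(edge_rows)) {
    if (edge_rows[j] > 0) m[seq_len(edge_rows[j]), j] <- TRUE
  }
  if (!is.null(extra_white)) m[extra_white] <- TRUE
  structure(
    list(mask = m, threshold_used = 0.5,
         times = (seq_along(edge_rows) - 1) / 217,
         velocities = v0 + (seq_len(n_rows) - 1) * dv),
    class = "tcd_mask"
  )
}

# Linear-power edge SNR estimator on a rendered scene (inverts the
# log-compression away from the clip).
estimate_edge_snr <- function(sp, env, dynamic_range = 40) {
  to_power <- function(i) 10^((i - 1) * dynamic_range / 10)
  v <- sp$velocities
  sig_rows <- v > 10 & v < min(env) - 5
  noise_rows <- v > max(env) + 10 & v < 140
  mean(to_power(sp$intensity[sig_rows, ])) /
    mean(to_power(sp$intensity[noise_rows, ]))
}

# Memoised scenes / pipeline runs shared across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

get_scene <- function(preset = "mca", seed = 1, duration = NULL) {
  key <- paste("scene", preset, seed, duration %||% "default", sep = "_")
  cached(key, {
    cfg <- if (is.null(duration)) scene_preset(preset, seed = seed) else
      scene_preset(preset, seed = seed, duration = duration)
    simulate_scene(cfg)
  })
}

get_traced <- function(preset = "mca", seed = 1, duration = NULL) {
  key <- paste("traced", preset, seed, duration %||% "default", sep = "_")
  cached(key, {
    scn <- get_scene(preset, seed, duration)
    seg <- if (is.null(duration)) 60 else duration
    estimate_envelope(scn$spectrogram, pipeline_config(segment_length = seg))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A clean physiological test beat at 217 Hz (40 -> 90 cm/s morphology).
test_beat <- function(len = 217, psv = 90, edv = 40) {
  t <- seq(0, 1, length.out = len + 1)[seq_len(len)]
  tr <- 0.15
  v <- numeric(len)
  up <- t < tr
  v[up] <- edv + (psv - edv) * (1 - cos(pi * t[up] / tr)) / 2
  v[!up] <- edv + (psv - edv) * exp(-(t[!up] - tr) / 0.2)
  v
}
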