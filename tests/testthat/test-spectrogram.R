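test_that("Doppler equation maps frequency shifts to velocities", {
  acq <- acquisition_params()
  expect_equal(freq_to_velocity(3472, acq), 152.768, tolerance = 1e-6)
  expect_identical(freq_to_velocity(0, acq), 0)
  # cos(60 deg) = 1/2 doubles the velocity for the same shift
  acq60 <- acquisition_params(insonation_angle = 60)
  expect_equal(freq_to_velocity(1000, acq60),
               2 * freq_to_velocity(1000, acq), tolerance = 1e-12)
  # linearity on random shifts
  set.seed(42)
  df <- stats::runif(20, -3000, 3000)
  a <- stats::runif(20, -5, 5)
  expect_equal(freq_to_velocity(a * df, acq), a * freq_to_velocity(df, acq),
               tolerance = 1e-12)
  expect_error(acquisition_params(insonation_angle = 90), "90")
  # inverse consistency
  expect_equal(velocity_to_freq(freq_to_velocity(1234, acq), acq), 1234,
               tolerance = 1e-9)
})

test_that("wall filter removes DC, preserves flow tones, halves at cutoff", {
  acq <- acquisition_params()
  fs <- acq$echo_sampling_rate
  t <- (0:(4 * fs - 1)) / fs
  mid <- seq(fs, 3 * fs)  # steady-state portion

  dc <- iq_signal(rep(1 + 1i, length(t)), fs, acq)
  expect_lt(max(Mod(wall_filter(dc)$samples[mid])), 1e-6)

  tone <- function(f) iq_signal(exp(2i * pi * f * t), fs, acq)
  amp500 <- max(Mod(wall_filter(tone(500))$samples[mid]))
  expect_equal(amp500, 1, tolerance = 0.01)
  amp100 <- max(Mod(wall_filter(tone(100))$samples[mid]))
  expect_equal(amp100, 0.5, tolerance = 0.01)

  # amplitude response matches the closed-form digital Butterworth magnitude
  for (f in c(60, 100, 150, 250, 400, 800, 1500)) {
    gain <- mean(Mod(wall_filter(tone(f))$samples[mid]))
    expect_equal(gain, oracle_hp2_filtfilt_gain(f, 100, fs),
                 tolerance = 1e-3)
  }
  expect_error(wall_filter(iq_signal(rep(1i, 5), fs, acq)), "short")
  expect_error(wall_filter(tone(100), cutoff = fs), "Nyquist")
})

test_that("spectrogram of a pure tone is a normalized ridge at 217 Hz", {
  acq <- acquisition_params()
  fs <- acq$echo_sampling_rate
  t <- (0:(fs - 1)) / fs
  iq <- iq_signal(exp(2i * pi * 1736 * t), fs, acq)
  sp <- compute_spectrogram(iq)

  expect_equal(ncol(sp$intensity), 217)
  expect_equal(max(sp$intensity), 1)
  expect_gte(min(sp$intensity), 0)

  ridge <- sp$velocities[apply(sp$intensity[, 50:150], 2, which.max)]
  expect_equal(mean(ridge), freq_to_velocity(1736, acq), tolerance = 0.2)
  expect_equal(freq_to_velocity(1736, acq), 76.384, tolerance = 1e-3)

  check <- diff(sp$velocities)
  expect_equal(max(check) - min(check), 0, tolerance = 1e-9)
  expect_equal(check[1], 0.2984, tolerance = 1e-3)

  expect_error(
    compute_spectrogram(iq_signal(rep(0i, fs), fs, acq)),
    "zero-power")
})

test_that("flow-region selection follows the dominant band and flips under mirroring", {
  acq <- acquisition_params()
  fs <- acq$echo_sampling_rate
  t <- (0:(2 * fs - 1)) / fs
  # energy at +40..+90 cm/s: sum of tones
  freqs <- velocity_to_freq(c(40, 60, 90), acq)
  x <- rowSums(sapply(freqs, function(f) exp(2i * pi * f * t)))
  sp_pos <- compute_spectrogram(iq_signal(x, fs, acq))
  expect_identical(select_flow_region(sp_pos)$sign, 1)

  # conjugation mirrors the spectrum about 0 Hz
  sp_neg <- compute_spectrogram(iq_signal(Conj(x), fs, acq))
  expect_identical(select_flow_region(sp_neg)$sign, -1)

  # exactly equal band energies tie to +1 (constructed, to make the tie exact)
  sym <- matrix(stats::runif(1024 * 10), nrow = 1024)
  v <- sp_pos$velocities
  band_pos <- which(v >= 5 & v <= 125)
  band_neg <- rev(which(v <= -5 & v >= -125))  # mirrored row for each
  sym[band_neg, ] <- sym[band_pos, ]
  sp_sym <- new_spectrogram(sym, times = (0:9) / 217, velocities = v)
  expect_identical(select_flow_region(sp_sym)$sign, 1)
})

test_that("spectrogram_band orients negative flow as ascending magnitudes", {
  scn <- get_scene("ica", seed = 2, duration = 8)
  band <- spectrogram_band(scn$spectrogram, -1, 5, Inf)
  expect_true(all(diff(band$velocities) > 0))
  expect_gte(min(band$velocities), 5)
  # the signal mass sits below the envelope magnitude
  col <- which.max(scn$true_envelope)
  sig_rows <- band$velocities < scn$true_envelope[col] - 5
  noise_rows <- band$velocities > scn$true_envelope[col] + 10
  expect_gt(mean(band$intensity[sig_rows, col]),
            mean(band$intensity[noise_rows, col]))
})
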