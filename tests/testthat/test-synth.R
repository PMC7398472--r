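test_that("ground-truth beats hit PSV and EDV and are seed-reproducible", {
  cfg <- scene_config(duration = 30, heart_rate = 60, seed = 5)
  truth <- generate_true_envelope(cfg)
  expect_lte(abs(length(truth$onsets) - 30), 1)

  on <- truth$onsets
  for (b in seq_len(length(on) - 1)) {
    seg <- truth$envelope[on[b]:(on[b + 1] - 1)]
    expect_equal(max(seg), cfg$psv, tolerance = 0.1 / cfg$psv)
    expect_equal(min(seg), cfg$edv, tolerance = 0.1 / cfg$edv)
  }
  expect_identical(truth, generate_true_envelope(cfg))
})

test_that("rendered scenes put the intensity edge at the true envelope", {
  # speckle off: salt pixels are a separate (and separately tested) artifact
  # that a plain column scan cannot be robust to
  cfg <- scene_config(duration = 8, seed = 2, speckle_prob = 0)
  scn <- simulate_scene(cfg)
  edge <- oracle_top_edge(scn$spectrogram)
  cols <- seq(10, length(edge) - 10, by = 7)
  err <- edge[cols] - scn$true_envelope[cols]
  expect_lt(stats::quantile(abs(err), 0.95),
            cfg$broadening_width + 2 * 0.2984)
})

test_that("the rendered noise floor matches the configured edge SNR", {
  cfg <- scene_config(duration = 8, seed = 2, speckle_prob = 0)
  scn <- simulate_scene(cfg)
  snr <- estimate_edge_snr(scn$spectrogram, scn$true_envelope)
  expect_equal(snr, 10^(cfg$edge_snr_db / 10), tolerance = 0.10)
})

test_that("dropout intervals attenuate the signal power before compression", {
  cfg_d <- scene_preset("dropout", seed = 6, duration = 8)
  cfg_c <- scene_preset("mca", seed = 6, duration = 8)
  sp_d <- simulate_scene(cfg_d)$spectrogram
  scn_c <- simulate_scene(cfg_c)
  sp_c <- scn_c$spectrogram
  to_power <- function(i) 10^((i - 1) * 40 / 10)
  v <- sp_c$velocities
  rows <- v > 10 & v < min(scn_c$true_envelope) - 5
  cols_in <- sp_c$times >= 2.2 & sp_c$times < 3.8
  ratio <- mean(to_power(sp_d$intensity[rows, cols_in])) /
    mean(to_power(sp_c$intensity[rows, cols_in]))
  att <- cfg_d$dropouts$attenuation[1]
  # the residual noise floor adds to both, so the ratio sits near
  # (att + noise) / (1 + noise)
  expect_lt(ratio, 3 * att + 0.02)
  cols_out <- sp_c$times >= 5 & sp_c$times < 7
  ratio_out <- mean(to_power(sp_d$intensity[rows, cols_out])) /
    mean(to_power(sp_c$intensity[rows, cols_out]))
  expect_equal(ratio_out, 1, tolerance = 0.05)
})

test_that("negative-flow scenes mirror the signal to negative velocities", {
  scn <- get_scene("ica", seed = 2, duration = 8)
  sp <- scn$spectrogram
  expect_identical(select_flow_region(sp)$sign, -1)
  neg_mass <- sum(sp$intensity[sp$velocities < -5 & sp$velocities > -125, ])
  pos_mass <- sum(sp$intensity[sp$velocities > 5 & sp$velocities < 125, ])
  expect_gt(neg_mass, pos_mass)
})

test_that("synthesized IQ reproduces the envelope edge end to end", {
  cfg <- scene_config(duration = 6, seed = 8, speckle_prob = 0)
  truth <- generate_true_envelope(cfg)
  iq <- synthesize_iq(truth, cfg)
  expect_length(iq$samples, round(cfg$duration * 6944))
  expect_identical(iq$samples, synthesize_iq(truth, cfg)$samples)

  sp <- compute_spectrogram(wall_filter(iq))
  # the stochastic plateau sits lower relative to the global maximum than in
  # the rendered scenes, so scan at a level between noise and plateau
  edge <- oracle_top_edge(sp, level = 0.6)
  n <- min(length(edge), length(truth$envelope))
  cols <- seq(20, n - 20, by = 11)
  err <- edge[cols] - truth$envelope[cols]
  expect_lt(median(abs(err)), 2 * cfg$broadening_width + 1)
})

test_that("scene configs validate their physiology", {
  expect_error(scene_config(psv = 40, edv = 40), "psv > edv")
  expect_error(scene_config(duration = 1), "two beats")
})
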