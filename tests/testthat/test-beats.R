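test_that("onset detection recovers the generator's beats to within 40 ms", {
  cfg <- scene_config(duration = 60, heart_rate = 60, seed = 7)
  truth <- generate_true_envelope(cfg)
  onsets <- detect_onsets(truth$envelope)
  expect_lte(abs(length(onsets) - length(truth$onsets)), 1)
  err_s <- vapply(onsets, function(o) min(abs(o - truth$onsets)), numeric(1)) /
    cfg$rate
  expect_lt(max(err_s), 0.040)
})

test_that("onset detection is scale invariant and silent on flat input", {
  cfg <- scene_config(duration = 30, seed = 4)
  env <- generate_true_envelope(cfg)$envelope
  expect_identical(detect_onsets(env), detect_onsets(2 * env))
  expect_identical(detect_onsets(rep(55, 217 * 5)), integer(0))
  expect_error(detect_onsets(rep(55, 100)), "2 s")
})

test_that("the four physiological screens fire with the right reason codes", {
  mk <- function(samples, dur) {
    n <- round(dur * 217)
    tibble::tibble(beat = 1L, onset_idx = 1L, end_idx = n, onset_s = 0,
                   duration_s = dur,
                   samples = list(rep_len(samples, n)))
  }
  beats <- dplyr::bind_rows(
    mk(test_beat(), 0.6),                   # healthy
    mk(test_beat(), 0.6),
    mk(test_beat(), 0.6),
    mk(c(0, 25), 0.6),                      # systolic max 25 < 30
    mk(c(65, 80), 0.6),                     # pulse 15 < 20
    mk(test_beat(), 0.2),                   # too short (also rel. band)
    mk(test_beat(), 1.5)                    # 1.5 > 2 x median (0.6)
  )
  beats$beat <- seq_len(nrow(beats))
  scr <- screen_beats(beats)
  expect_equal(scr$passed, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_match(scr$reasons[4], "1")
  expect_match(scr$reasons[5], "2")
  expect_match(scr$reasons[6], "3")
  expect_identical(scr$reasons[7], "4")
})

test_that("template is the zero-padded median truncated to the median length", {
  b <- list(rep(50, 130), rep(50, 130), rep(50, 131))
  tpl <- build_template(b)
  expect_length(tpl, 130)
  expect_equal(tpl, rep(50, 130))
  # identical beats reproduce the beat
  one <- test_beat(140)
  expect_equal(build_template(list(one, one, one)), one)
  expect_error(build_template(list()), "no valid beats")
})

test_that("NMSE is windowed to the first 75% of the template", {
  tpl <- test_beat(100)
  expect_equal(normalized_mse(tpl, tpl), 0)
  expect_equal(normalized_mse(2 * tpl, tpl), 1)
  tail_off <- tpl
  tail_off[80:100] <- tpl[80:100] + 25    # beyond floor(0.75 * 100) = 75
  expect_equal(normalized_mse(tail_off, tpl), 0)
  expect_error(normalized_mse(tpl, rep(0, 100)), "all-zero")
  expect_error(normalized_mse(tpl, tpl, fraction = 0), "fraction")
})

test_that("quality assessment flags dropouts and scores template mismatch", {
  beat <- test_beat(130)
  n_beats <- 20
  env <- rep(beat, n_beats + 1)
  onsets <- seq(1, by = 130, length.out = n_beats + 1)

  rep_clean <- assess_quality(env, onsets)
  expect_equal(rep_clean$artifact_index, 0)
  expect_equal(rep_clean$n_beats, n_beats)
  expect_true(all(rep_clean$beats$sqi > 99.9))

  # half the beats replaced by a flat 10 cm/s dropout
  env_drop <- env
  for (b in seq(2, n_beats, by = 2)) {
    env_drop[onsets[b]:(onsets[b + 1] - 1)] <- 10
  }
  rep_drop <- assess_quality(env_drop, onsets)
  expect_equal(rep_drop$artifact_index, 50)

  # one beat scaled so its windowed NMSE is exactly 0.2: SQI 80, unflagged
  env_sc <- env
  env_sc[onsets[5]:(onsets[6] - 1)] <- beat * (1 + sqrt(0.2))
  rep_sc <- assess_quality(env_sc, onsets)
  expect_equal(rep_sc$beats$nmse[5], 0.2, tolerance = 1e-9)
  expect_equal(rep_sc$beats$sqi[5], 80, tolerance = 1e-6)
  expect_false(rep_sc$beats$artifact[5])
  # artifact index equals a direct recount
  expect_equal(rep_sc$artifact_index,
               100 * sum(rep_sc$beats$artifact) / nrow(rep_sc$beats))
})

test_that("candidate selection minimizes the artifact index with documented ties", {
  mk <- function(g, ai) list(gamma = g, artifact_index = ai)
  reps <- list(mk(0.36, 10), mk(0.38, 0), mk(0.40, 40))
  expect_identical(select_best_candidate(reps, 0.40), 2L)
  ties <- list(mk(0.36, 5), mk(0.40, 5), mk(0.44, 5))
  expect_identical(select_best_candidate(ties, 0.40), 2L)  # gamma_Otsu itself
  expect_identical(select_best_candidate(list(mk(0.5, 80)), 0.5), 1L)
})
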