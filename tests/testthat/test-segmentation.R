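test_that("Otsu threshold equals the exhaustive within-class-variance scan", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(200:2000, 1)
    x <- switch(i %% 3 + 1,
                stats::runif(n),
                pmin(pmax(c(stats::rnorm(n, 0.3, 0.1),
                            stats::rnorm(n, 0.75, 0.08)), 0), 1),
                stats::rbeta(n, 2, 5))
    expect_identical(as.numeric(otsu_threshold(x)), oracle_otsu(x))
  }
})

test_that("Otsu separates a two-mass distribution and degenerates gracefully", {
  x <- c(rep(0.2, 600), rep(0.8, 400))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.8)
  expect_identical(as.numeric(thr), oracle_otsu(x))

  expect_warning(thr_c <- otsu_threshold(rep(0.5, 100)), "degenerate")
  expect_equal(as.numeric(thr_c), 0.5)
  expect_true(attr(thr_c, "degenerate"))

  set.seed(11)
  mix <- pmin(pmax(c(stats::rnorm(5e4, 0.3, 0.05),
                     stats::rnorm(5e4, 0.7, 0.05)), 0), 1)
  expect_lt(abs(as.numeric(otsu_threshold(mix)) - 0.5), 0.02)
})

test_that("threshold grid is the clipped, sorted multiplicative family", {
  g <- make_threshold_grid(0.40)
  expect_equal(g$thresholds, c(0.36, 0.38, 0.40, 0.42, 0.44),
               tolerance = 1e-12)
  g2 <- make_threshold_grid(0.99)
  expect_equal(max(g2$thresholds), 1)
  expect_warning(g0 <- make_threshold_grid(0), "degenerate")
  expect_equal(g0$thresholds, rep(0, 5))
  expect_true(g0$degenerate)
})

test_that("binarization uses >= and is monotone in the threshold", {
  scn <- get_scene("mca", seed = 2, duration = 8)
  band <- spectrogram_band(scn$spectrogram, 1, 5, Inf)
  expect_true(all(binarize(band, 0)$mask))
  expect_false(any(binarize(band, 1.0001)$mask))
  thrs <- sort(stats::runif(4))
  masks <- lapply(thrs, function(g) binarize(band, g)$mask)
  for (i in seq_len(length(thrs) - 1)) {
    expect_true(all(masks[[i]] | !masks[[i + 1]]))  # mask(g2) subset of mask(g1)
  }
})

test_that("despeckle kernel is 7 x 17 pixels at the default axes", {
  expect_identical(tcdenv:::nearest_odd(0.03 * 217), 7L)
  expect_identical(tcdenv:::nearest_odd(5 / 0.298375), 17L)
})

test_that("despeckle removes isolated pixels, keeps large blocks, is idempotent", {
  m <- edge_mask(rep(0, 60), n_rows = 80)
  m$mask[40, 30] <- TRUE                 # isolated speckle
  m$mask[10:35, 10:50] <- TRUE           # solid block
  d <- despeckle(m)
  expect_identical(dim(d$mask), dim(m$mask))
  expect_false(d$mask[40, 30])
  expect_true(all(d$mask[18:27, 20:40])) # block interior untouched

  # a straight edge is a fixed point of the majority filter
  e <- edge_mask(rep(30, 60), n_rows = 80)
  e1 <- despeckle(e)
  expect_identical(e1$mask, e$mask)
  expect_identical(despeckle(e1)$mask, e1$mask)

  tiny <- edge_mask(rep(2, 3), n_rows = 5)
  expect_error(despeckle(tiny), "larger than mask")
})
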