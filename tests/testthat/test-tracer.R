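test_that("column candidates are the top white pixels, descending", {
  cfg <- tracer_config()
  col <- rep(FALSE, 200)
  col[c(10, 40, 80, 120, 150, 180)] <- TRUE
  vels <- 5 + (0:199) * 0.3
  cand <- column_candidates(col, vels, cfg)
  expect_equal(cand, vels[c(180, 150, 120, 80, 40)])  # 5 highest, descending
  expect_length(column_candidates(rep(FALSE, 200), vels, cfg), 0)
  col3 <- rep(FALSE, 200); col3[c(5, 50, 90)] <- TRUE
  expect_length(column_candidates(col3, vels, cfg), 3)
  # pixels above v_start are never candidates
  colhi <- rep(FALSE, 600); velhi <- 5 + (0:599) * 0.3  # up to 184.7 cm/s
  colhi[c(100, 580)] <- TRUE
  expect_equal(column_candidates(colhi, velhi, cfg), velhi[100])
})

test_that("a clean constant edge is traced exactly with no flags", {
  m <- edge_mask(rep(120, 100))
  env <- trace_envelope(m)
  expect_equal(env$velocities, rep(m$velocities[120], 100))
  expect_false(any(env$held))
  expect_false(any(env$override))
})

test_that("an isolated pixel without white support below it is rejected", {
  # edge at row 100; speckle 25 bins above it (black below the speckle):
  # only 16 of the 40 support bins are white, short of the >20 majority
  m <- edge_mask(rep(100, 50))
  m$mask[125, 25] <- TRUE
  env <- trace_envelope(m)
  expect_equal(env$velocities, rep(m$velocities[100], 50))
})

test_that("a one-column jump beyond 30 cm/s is held from the previous value", {
  edges <- rep(100, 40)
  edges[20] <- 100 + ceiling(50 / 0.3)   # +50 cm/s for one column
  m <- edge_mask(edges, n_rows = 400)
  env <- trace_envelope(m)
  expect_equal(env$velocities[20], env$velocities[19])
  expect_true(env$held[20])
  expect_false(any(env$held[-20]))
})

test_that("a sustained jump is held for 20 columns then overridden", {
  jump_bins <- ceiling(50 / 0.3)
  edges <- c(rep(100, 30), rep(100 + jump_bins, 60))
  m <- edge_mask(edges, n_rows = 400)
  env <- trace_envelope(m)
  v_old <- m$velocities[100]
  v_new <- m$velocities[100 + jump_bins]
  expect_equal(env$velocities[31:50], rep(v_old, 20))   # held columns
  expect_true(all(env$held[31:50]))
  expect_equal(env$velocities[51], v_new)               # 21st column overrides
  expect_true(env$override[51])
  expect_false(any(env$override[-51]))
  expect_equal(env$velocities[60:90], rep(v_new, 31))   # re-anchored
})

test_that("continuity invariant holds wherever no flag is set", {
  cfg <- tracer_config()
  set.seed(3)
  for (rep_i in 1:5) {
    edges <- pmax(20, pmin(380, cumsum(c(150, sample(-30:30, 99, TRUE)))))
    m <- edge_mask(edges, n_rows = 400)
    env <- trace_envelope(m, cfg)
    for (k in 4:length(env$velocities)) {
      if (!env$held[k] && !env$override[k]) {
        expect_lte(abs(env$velocities[k] - mean(env$velocities[(k - 3):(k - 1)])),
                   cfg$max_step_dev + 1e-9)
      }
    }
  }
})

test_that("on gentle staircases the tracer equals the top-edge oracle", {
  set.seed(9)
  # steps of at most 30 cm/s with plateaus of at least 4 columns
  steps <- sample(seq(-30, 30, by = 10), 12, replace = TRUE)
  edges <- rep(pmax(30, pmin(350, cumsum(c(150, steps)))), each = 6)
  m <- edge_mask(edges, n_rows = 400)
  env <- trace_envelope(m)
  oracle <- apply(m$mask, 2, function(col) m$velocities[max(which(col))])
  expect_equal(env$velocities, oracle)
  # determinism
  expect_identical(env, trace_envelope(m))
})

test_that("degenerate masks error or bootstrap to zero", {
  m0 <- edge_mask(integer(0))
  expect_error(trace_envelope(m0), "column")
  m_black <- edge_mask(rep(0, 30))
  env <- trace_envelope(m_black)
  expect_equal(env$velocities, rep(0, 30))
  expect_true(all(env$held))
})
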