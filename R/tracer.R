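#' Envelope tracer settings
#'
#' Constants of the physiologically-constrained edge following. Per column, up
#' to `n_candidates` white pixels are collected scanning downward from
#' `v_start`; a candidate is accepted if (1) strictly more than
#' `support_majority` of the `support_bins` velocity bins directly below it are
#' white (speckle rejection; 40 bins is about 12 cm/s at the default velocity
#' resolution) and (2) it deviates by at most `max_step_dev` from the mean of
#' the previous `lookback` accepted values (about 14 ms of history at 217 Hz;
#' outlier rejection). If no candidate passes for more than `override_after`
#' consecutive columns, the maximal candidate is taken regardless, letting the
#' trace re-anchor after genuine jumps.
#'
#' @param n_candidates Candidates examined per column.
#' @param support_bins Bins below the candidate inspected by check 1.
#' @param support_majority Required white fraction, strictly exceeded.
#' @param max_step_dev Maximal deviation from recent history, cm/s.
#' @param lookback History length in samples for check 2.
#' @param override_after Consecutive failing columns before the override.
#' @param v_start Scan start velocity, cm/s.
#' @return An object of class `tcd_tracer_config`.
#' @export
tracer_config <- function(n_candidates = 5, support_bins = 40,
                          support_majority = 0.5, max_step_dev = 30,
                          lookback = 3, override_after = 20, v_start = 152) {
  stopifnot(n_candidates >= 1, support_bins >= 1, max_step_dev > 0,
            lookback >= 1, override_after >= 1, v_start > 0)
  if (support_majority <= 0 || support_majority > 1) {
    abort("support_majority must lie in (0, 1]")
  }
  structure(
    list(n_candidates = n_candidates, support_bins = support_bins,
         support_majority = support_majority, max_step_dev = max_step_dev,
         lookback = lookback, override_after = override_after,
         v_start = v_start),
    class = "tcd_tracer_config"
  )
}

#' Candidate velocities of one mask column
#'
#' Scans a magnitude-oriented mask column downward from `cfg$v_start` and
#' returns up to `cfg$n_candidates` white-pixel velocities in strictly
#' descending order.
#'
#' @param mask_column Logical vector, one entry per velocity bin (ascending).
#' @param velocities Bin velocities, cm/s, ascending, same length.
#' @param cfg [tracer_config()] object.
#' @return Numeric vector of candidate velocities (possibly empty).
#' @export
column_candidates <- function(mask_column, velocities, cfg = tracer_config()) {
  idx <- column_candidate_rows(mask_column, velocities, cfg)
  velocities[idx]
}

column_candidate_rows <- function(mask_column, velocities, cfg) {
  top <- which(velocities <= cfg$v_start)
  if (length(top) == 0L) return(integer(0))
  top <- max(top)
  white <- which(mask_column[seq_len(top)])
  if (length(white) == 0L) return(integer(0))
  rev(tail(white, cfg$n_candidates))
}

#' Trace the raw maximal-velocity envelope of a binary mask
#'
#' Column-by-column edge following under the two sanity checks described in
#' [tracer_config()]. When no candidate passes both checks the previous value
#' is held (`held` flag); when that has happened for more than
#' `override_after` consecutive columns the maximal candidate is taken
#' regardless (`override` flag) and the failure counter resets. Bins below the
#' band floor count as white for the support check, so low-velocity edges near
#' the wall-filter stop band are not unfairly rejected. For the first
#' `lookback` columns the continuity check is skipped (no history); the first
#' value is the highest candidate passing the support check, else 0.
#'
#' @param mask [despeckle()]d `tcd_mask`, magnitude-oriented (velocities
#'   ascending magnitudes).
#' @param cfg [tracer_config()] object.
#' @return An object of class `tcd_raw_envelope`: list with `velocities`
#'   (cm/s per column), `held` and `override` (logical per column), `times`.
#' @export
trace_envelope <- function(mask, cfg = tracer_config()) {
  stopifnot(inherits(mask, "tcd_mask"))
  m <- mask$mask
  vels <- mask$velocities
  n_cols <- ncol(m)
  if (n_cols == 0L) abort("mask has no columns")
  nb <- cfg$support_bins
  need <- cfg$support_majority * nb

  # cumulative white counts per column for O(1) support queries
  csum <- apply(m, 2, cumsum)
  csum <- rbind(0, csum)

  v_hat <- numeric(n_cols)
  held <- logical(n_cols)
  override <- logical(n_cols)
  fail_count <- 0L

  for (k in seq_len(n_cols)) {
    rows <- column_candidate_rows(m[, k], vels, cfg)
    chosen <- NA_real_
    if (length(rows) > 0L) {
      hist_ok <- k <= cfg$lookback
      hist_mean <- if (!hist_ok) {
        mean(v_hat[(k - cfg$lookback):(k - 1L)])
      } else NA_real_
      for (r in rows) {
        lo <- max(1L, r - nb)
        support <- (csum[r, k] - csum[lo, k]) + (nb - (r - lo))
        if (support <= need) next
        if (!hist_ok && abs(vels[r] - hist_mean) > cfg$max_step_dev) next
        chosen <- vels[r]
        break
      }
    }
    if (!is.na(chosen)) {
      v_hat[k] <- chosen
      fail_count <- 0L
    } else {
      fail_count <- fail_count + 1L
      if (fail_count > cfg$override_after && length(rows) > 0L) {
        v_hat[k] <- vels[rows[1L]]
        override[k] <- TRUE
        fail_count <- 0L
      } else {
        v_hat[k] <- if (k > 1L) v_hat[k - 1L] else 0
        held[k] <- TRUE
        # keep the counter saturated so the next column with any candidate
        # can fire the override immediately
        if (fail_count > cfg$override_after + 1L) {
          fail_count <- cfg$override_after + 1L
        }
      }
    }
  }
  structure(
    list(velocities = v_hat, held = held, override = override,
         times = mask$times),
    class = "tcd_raw_envelope"
  )
}
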