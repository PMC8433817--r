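#' Event-calling configuration
#'
#' Parameters of the two-stage caller: first find the probable region from
#' the model's probability trace, then search the raw signal locally for the
#' exact timepoint.
#'
#' @param probability_threshold trace probability above which a frame belongs
#'   to a candidate region, in (0, 1); default 0.5.
#' @param min_separation_s events closer than this are merged, keeping the
#'   one with higher probability; default 0.4 s (below any plausible interval
#'   between successive same-phase events of one leg).
#' @param refine_window_s half-width of the local search on the raw
#'   angular-velocity magnitude; default 0.3 s.
#' @param refine_min_height_frac only raw-signal local maxima reaching this
#'   fraction of the search window's maximum count as refinement candidates;
#'   the default 0.35 sits above the noise floor but below the smallest
#'   genuine flank-to-window-maximum ratio the step morphology produces
#'   (an initial step's reduced foot-off peak against its mid-swing peak).
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(probability_threshold = 0.5,
                          min_separation_s = 0.4,
                          refine_window_s = 0.3,
                          refine_min_height_frac = 0.35) {
  stopifnot(probability_threshold > 0, probability_threshold < 1,
            min_separation_s > 0, refine_window_s > 0,
            refine_min_height_frac > 0, refine_min_height_frac <= 1)
  structure(list(probability_threshold = probability_threshold,
                 min_separation_s = min_separation_s,
                 refine_window_s = refine_window_s,
                 refine_min_height_frac = refine_min_height_frac),
            class = "caller_config")
}

#' Call discrete gait events from a probability trace
#'
#' Each probability peak (local maximum of the trace, plateau runs counted
#' once at their center) whose probability reaches the threshold becomes a
#' candidate event; candidates closer than `min_separation_s` are then merged,
#' keeping the higher-probability one (ties: the earlier frame). Because the
#' peak set and the separation merge do not depend on the threshold, raising
#' the threshold can only remove events, never add or move them -- the
#' monotonicity that a literal "supra-threshold region" formulation lacks
#' (one region may split in two as the threshold rises).
#'
#' @param trace a `prediction_trace`.
#' @param cfg a [caller_config()].
#' @param side side label attached to the returned events.
#' @return A [gait_events()] data frame with an extra `prob` column, sorted
#'   by frame (possibly zero rows).
#' @export
call_events <- function(trace, cfg = caller_config(), side = "left") {
  p <- trace$probabilities
  cand <- local_maxima(p)
  # suppress near-coincident peaks first (threshold-independent), keeping the
  # higher-probability one, ties toward the earlier frame
  min_sep <- round(cfg$min_separation_s * trace$sampling_rate_hz)
  kept <- integer(0)
  for (i in cand[order(-p[cand], cand)]) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  kept <- sort(kept[p[kept] >= cfg$probability_threshold])
  ev <- gait_events(trace$frames[kept],
                    rep(trace$phase %||% "MidS", length(kept)), side, TRUE)
  ev$prob <- p[kept]
  ev
}

#' Refine called events on the raw angular-velocity magnitude
#'
#' The trace localizes events only as precisely as the smoothed features
#' allow; each called event is therefore moved to the nearest substantial
#' local maximum of the raw (unsmoothed) angular-velocity magnitude within
#' `refine_window_s` of its frame -- "substantial" meaning at least
#' `refine_min_height_frac` of the window's maximum, so noise wiggles are
#' skipped. The nearest (not the highest) qualifying peak is chosen because
#' the much larger mid-swing peak sits only ~0.3 s from the foot-off and
#' foot-contact peaks and would otherwise capture them. An event already on
#' a local maximum is unchanged, and no event can move farther than the
#' window half-width; a window with no interior peak falls back to its
#' maximum sample.
#'
#' @param events event table from [call_events()].
#' @param ang_vel_mag_raw raw angular-velocity magnitude of the recording.
#' @param cfg a [caller_config()].
#' @param sampling_rate_hz sampling rate in Hz.
#' @return The event table with refined frames, sorted by frame.
#' @export
refine_on_signal <- function(events, ang_vel_mag_raw, cfg = caller_config(),
                             sampling_rate_hz = 100) {
  if (nrow(events) == 0L) return(events)
  w <- round(cfg$refine_window_s * sampling_rate_hz)
  n <- length(ang_vel_mag_raw)
  events$frame <- vapply(events$frame, function(f) {
    lo <- max(0L, f - w); hi <- min(n - 1L, f + w)
    seg <- ang_vel_mag_raw[(lo:hi) + 1L]
    cand <- local_maxima(seg)
    cand <- cand[seg[cand] >= cfg$refine_min_height_frac * max(seg)]
    if (!length(cand)) return(as.integer(lo + which.max(seg) - 1L))
    pos <- f - lo + 1L
    as.integer(lo + cand[which.min(abs(cand - pos))] - 1L)
  }, integer(1))
  events[order(events$frame), , drop = FALSE]
}

#' Event-level agreement between predicted and reference events
#'
#' Greedy one-to-one matching: among all prediction/reference pairs within
#' `tolerance_frames`, repeatedly match the pair with the smallest absolute
#' timing difference (ties: earlier reference, then earlier prediction) until
#' none remain. Precision, recall and F1 follow from the matched counts; the
#' mean absolute timing error is computed over matched pairs only. Greedy
#' nearest-first matching coincides with optimal assignment whenever
#' reference events are separated by more than twice the tolerance, which
#' gait periodicity guarantees at sensible tolerances.
#'
#' @param predicted,truth event data frames (column `frame`), each sorted.
#' @param tolerance_frames maximum |timing difference| for a match; default 5
#'   frames (50 ms at 100 Hz).
#' @return List with `precision`, `recall`, `f1`,
#'   `mean_abs_timing_error_frames`, `n_matched`, and the `matches` pairs.
#' @export
evaluate_events <- function(predicted, truth, tolerance_frames = 5) {
  pf <- as.integer(predicted$frame)
  tf <- as.integer(truth$frame)
  np <- length(pf); nt <- length(tf)
  pairs <- expand.grid(ti = seq_len(nt), pi = seq_len(np))
  if (nrow(pairs)) {
    pairs$d <- abs(tf[pairs$ti] - pf[pairs$pi])
    pairs <- pairs[pairs$d <= tolerance_frames, , drop = FALSE]
    pairs <- pairs[order(pairs$d, pairs$ti, pairs$pi), , drop = FALSE]
  }
  used_t <- logical(nt); used_p <- logical(np)
  mt <- mp <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    ti <- pairs$ti[k]; pi <- pairs$pi[k]
    if (used_t[ti] || used_p[pi]) next
    used_t[ti] <- TRUE; used_p[pi] <- TRUE
    mt <- c(mt, ti); mp <- c(mp, pi)
  }
  nm <- length(mt)
  precision <- if (np) nm / np else if (nt) 0 else 1
  recall <- if (nt) nm / nt else if (np) 0 else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  mae <- if (nm) mean(abs(tf[mt] - pf[mp])) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       mean_abs_timing_error_frames = mae, n_matched = nm,
       matches = data.frame(truth_frame = tf[mt], predicted_frame = pf[mp]))
}
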