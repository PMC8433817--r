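#' Labeler configuration
#'
#' Detection parameters for the deterministic peak-based phase labeler. None
#' of these is dictated by the underlying method description, which is
#' narrative; they are package defaults, logged into run metadata so every
#' labeling run is reproducible.
#'
#' @param mids_min_prominence mid-swing peaks must rise above this fraction of
#'   the signal's range (above its minimum) to count. Default 0.1.
#' @param mids_min_separation_s minimum separation between mid-swing peaks in
#'   seconds; closer peaks are suppressed keeping the higher one. At ordinary
#'   cadence this also suppresses the foot-off/foot-contact flank peaks, which
#'   sit within ~0.35 s of their swing peak. Default 0.4.
#' @param flank_search_max_s how far from each mid-swing peak the flanking
#'   foot-off / foot-contact peaks are searched, seconds. Default 0.8.
#' @param turning_threshold deviation of the bilateral rotation-matrix
#'   magnitude from its straight-walking baseline that flags turning
#'   (dimensionless; the magnitude itself is bounded by sqrt(2)). Default 0.25.
#' @param turning_min_duration_s minimum sustained deviation to accept a
#'   turning interval, seconds. Default 0.5.
#' @param turning_pad_s padding added to each side of a detected turning
#'   interval, seconds, so that steps at the very start or end of a turn are
#'   also excluded. Default 0.5.
#' @param rest_gap_s rest gap separating walking bouts, used to classify
#'   initial/terminal steps. Default 2.0 (the protocol's between-task pause).
#' @return A list of class `labeler_config`.
#' @export
labeler_config <- function(mids_min_prominence = 0.1,
                           mids_min_separation_s = 0.4,
                           flank_search_max_s = 0.8,
                           turning_threshold = 0.25,
                           turning_min_duration_s = 0.5,
                           turning_pad_s = 0.5,
                           rest_gap_s = 2.0) {
  vals <- list(mids_min_prominence = mids_min_prominence,
               mids_min_separation_s = mids_min_separation_s,
               flank_search_max_s = flank_search_max_s,
               turning_threshold = turning_threshold,
               turning_min_duration_s = turning_min_duration_s,
               turning_pad_s = turning_pad_s,
               rest_gap_s = rest_gap_s)
  if (any(unlist(vals) <= 0)) stop("all labeler parameters must be positive")
  structure(vals, class = "labeler_config")
}

# 1-based indices of local maxima; plateaus yield their central index
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  s <- sign(diff(x))
  idx <- which(s != 0)
  if (length(idx) < 2L) return(integer(0))
  sv <- s[idx]
  turn <- which(sv[-length(sv)] > 0 & sv[-1] < 0)
  if (!length(turn)) return(integer(0))
  a <- idx[turn] + 1L        # first index of the peak plateau
  b <- idx[turn + 1L]        # last index of the peak plateau
  as.integer(floor((a + b) / 2))
}

#' Detect mid-swing peaks on the smoothed angular-velocity magnitude
#'
#' Mid-swing is the swing-phase peak of the angular-velocity magnitude. Local
#' maxima above `mids_min_prominence` of the signal's range are kept, then
#' peaks closer than `mids_min_separation_s` are suppressed, always keeping
#' the higher one (ties: the earlier). The separation rule is what rejects the
#' lower foot-off/foot-contact flank peaks of the same step.
#'
#' @param x smoothed, nonnegative angular-velocity magnitude.
#' @param cfg a [labeler_config()].
#' @param sampling_rate_hz sampling rate in Hz.
#' @return Sorted integer vector of 0-based frames (possibly empty).
#' @export
detect_mids <- function(x, cfg = labeler_config(), sampling_rate_hz = 100) {
  r <- range(x)
  if (r[1] == r[2]) return(integer(0))
  thr <- r[1] + cfg$mids_min_prominence * (r[2] - r[1])
  cand <- local_maxima(x)
  cand <- cand[x[cand] >= thr]
  if (!length(cand)) return(integer(0))
  min_sep <- round(cfg$mids_min_separation_s * sampling_rate_hz)
  ord <- cand[order(-x[cand], cand)]  # by height desc, then position
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept) - 1L
}

# pick the flank peak inside (lo, hi) exclusive 0-based bounds:
# highest local maximum, ties broken toward `center`
pick_flank <- function(x, lo, hi, center) {
  if (hi - lo < 2L) return(NA_integer_)
  cand <- local_maxima(x) - 1L
  cand <- cand[cand > lo & cand < hi]
  if (!length(cand)) return(NA_integer_)
  h <- x[cand + 1L]
  best <- which(h == max(h))
  if (length(best) > 1L) best <- best[which.min(abs(cand[best] - center))]
  cand[best]
}

#' Locate foot-off and foot-contact flanking each mid-swing peak
#'
#' Foot-off is the moment the foot leaves the ground and foot-contact the
#' moment it touches down again; on the smoothed angular-velocity magnitude
#' they appear as the peaks flanking each swing peak. For each mid-swing frame
#' the left flank is searched in `(mids - flank_search_max, mids)` and the
#' right flank in `(mids, mids + flank_search_max)`; each window is
#' additionally clipped at the midpoint toward the adjacent mid-swing peak, so
#' a flank peak is always attributed to the nearer swing (without the clip,
#' the next step's higher foot-off peak can fall inside this step's
#' foot-contact window at ordinary cadence). Within the clipped window the
#' highest local maximum wins, ties broken toward the mid-swing frame.
#' Mid-swing peaks lacking either flank are dropped with a message.
#'
#' @param x smoothed angular-velocity magnitude.
#' @param mids_frames 0-based mid-swing frames from [detect_mids()].
#' @param cfg a [labeler_config()].
#' @param sampling_rate_hz sampling rate in Hz.
#' @return A data frame with columns `fo`, `mids`, `fc` (0-based frames), one
#'   row per retained step, ordered by `fo`.
#' @export
detect_fo_fc <- function(x, mids_frames, cfg = labeler_config(),
                         sampling_rate_hz = 100) {
  flank <- round(cfg$flank_search_max_s * sampling_rate_hz)
  m <- sort(as.integer(mids_frames))
  k <- length(m)
  fo <- fc <- rep(NA_integer_, k)
  for (j in seq_len(k)) {
    lo <- m[j] - flank
    if (j > 1L) lo <- max(lo, (m[j - 1L] + m[j]) %/% 2L)
    hi <- m[j] + flank
    if (j < k) hi <- min(hi, (m[j] + m[j + 1L]) %/% 2L)
    fo[j] <- pick_flank(x, lo, m[j], m[j])
    fc[j] <- pick_flank(x, m[j], hi, m[j])
  }
  drop <- is.na(fo) | is.na(fc)
  if (any(drop))
    message(sprintf("dropping %d mid-swing peak(s) lacking a flank (frames: %s)",
                    sum(drop), paste(m[drop], collapse = ", ")))
  data.frame(fo = fo[!drop], mids = m[!drop], fc = fc[!drop])
}

#' Detect turning intervals from the bilateral rotation-matrix magnitude
#'
#' During straight walking the bilateral direction-cosine magnitude stays
#' near a constant baseline; while turning it deviates as the heading sweeps.
#' The baseline is estimated in two passes (median of the whole signal, then
#' median outside candidate intervals). Frames whose absolute deviation
#' exceeds `turning_threshold` for at least `turning_min_duration_s` form core
#' intervals; each core is grown outward while the deviation stays above half
#' the threshold (hysteresis) and finally padded by `turning_pad_s`, because
#' the deviation necessarily starts from zero at the edges of a heading sweep.
#' Overlapping intervals are merged.
#'
#' @param x smoothed bilateral rotation-matrix magnitude.
#' @param cfg a [labeler_config()].
#' @param sampling_rate_hz sampling rate in Hz.
#' @return A data frame with columns `start`, `end` (0-based frames,
#'   inclusive); zero rows if no turning is found.
#' @export
detect_turning <- function(x, cfg = labeler_config(), sampling_rate_hz = 100) {
  min_dur <- round(cfg$turning_min_duration_s * sampling_rate_hz)
  pad <- round(cfg$turning_pad_s * sampling_rate_hz)
  find_intervals <- function(baseline) {
    dev <- abs(x - baseline)
    core <- dev > cfg$turning_threshold
    r <- rle(core)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_dur
    if (!any(keep)) return(data.frame(start = integer(0), end = integer(0)))
    s <- starts[keep]; e <- ends[keep]
    # hysteresis: extend while deviation exceeds half the threshold
    lowdev <- dev > cfg$turning_threshold / 2
    for (i in seq_along(s)) {
      while (s[i] > 1L && lowdev[s[i] - 1L]) s[i] <- s[i] - 1L
      while (e[i] < length(x) && lowdev[e[i] + 1L]) e[i] <- e[i] + 1L
    }
    s <- pmax(1L, s - pad); e <- pmin(length(x), e + pad)
    merge_intervals(s, e)
  }
  pass1 <- find_intervals(stats::median(x))
  outside <- rep(TRUE, length(x))
  for (i in seq_len(nrow(pass1)))
    outside[(pass1$start[i] + 1L):(pass1$end[i] + 1L)] <- FALSE
  baseline <- if (any(outside)) stats::median(x[outside]) else stats::median(x)
  find_intervals(baseline)
}

# merge overlapping/adjacent [s, e] (1-based in, 0-based out)
merge_intervals <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me + 1L) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  data.frame(start = c(out_s, ms) - 1L, end = c(out_e, me) - 1L)
}

#' Classify steps as initial, steady or terminal
#'
#' A step is `initial` when no other step ends within `rest_gap_s` before its
#' foot-off (the first step after a rest), `terminal` when no step begins
#' within `rest_gap_s` after its foot-contact (the last step before a rest),
#' and `steady` otherwise. A lone step, which is both, is labeled `terminal`.
#'
#' @param steps data frame with columns `fo`, `mids`, `fc` sorted by `fo`.
#' @param cfg a [labeler_config()].
#' @param sampling_rate_hz sampling rate in Hz.
#' @return `steps` with a `step_type` column added.
#' @export
classify_step_type <- function(steps, cfg = labeler_config(),
                               sampling_rate_hz = 100) {
  gap <- cfg$rest_gap_s * sampling_rate_hz
  n <- nrow(steps)
  if (n == 0L) { steps$step_type <- character(0); return(steps) }
  prev_fc <- c(-Inf, steps$fc[-n])
  next_fo <- c(steps$fo[-1], Inf)
  is_initial <- (steps$fo - prev_fc) > gap
  is_terminal <- (next_fo - steps$fc) > gap
  steps$step_type <- ifelse(is_terminal, "terminal",
                            ifelse(is_initial, "initial", "steady"))
  steps
}

#' Flag steps that fall inside turning intervals as invalid
#'
#' Only steps taken while walking straight ahead are valid; a step is invalid
#' as soon as any of its three event frames lies inside a detected turning
#' interval. Invalid steps keep their events but are excluded from the label
#' channels.
#'
#' @param steps step data frame (`fo`, `mids`, `fc`, ...).
#' @param turning data frame of turning intervals from [detect_turning()].
#' @return `steps` with a logical `valid` column.
#' @export
validate_steps <- function(steps, turning) {
  in_turn <- function(f) {
    if (nrow(turning) == 0L) return(rep(FALSE, length(f)))
    vapply(f, function(fr) any(fr >= turning$start & fr <= turning$end),
           logical(1))
  }
  steps$valid <- !(in_turn(steps$fo) | in_turn(steps$mids) | in_turn(steps$fc))
  steps
}

#' Binary per-phase label channels
#'
#' One 0/1 channel per phase, of length `n_frames`, with 1 exactly at the
#' event frames of valid steps (phase frames labeled 1, everything else 0).
#'
#' @param steps validated step data frame.
#' @param n_frames series length.
#' @return An object of class `labeled_series`: list with binary vectors
#'   `fo`, `mids`, `fc` and the `n_frames`.
#' @export
make_label_channels <- function(steps, n_frames) {
  valid <- steps[steps$valid, , drop = FALSE]
  mk <- function(frames) {
    if (length(frames) && any(frames >= n_frames | frames < 0))
      stop("event frame outside the series")
    ch <- integer(n_frames)
    ch[frames + 1L] <- 1L
    ch
  }
  structure(list(fo = mk(valid$fo), mids = mk(valid$mids), fc = mk(valid$fc),
                 n_frames = n_frames),
            class = "labeled_series")
}

#' Run the full labeler on one leg's feature set
#'
#' Detects mid-swing peaks, locates their foot-off/foot-contact flanks,
#' classifies step types, invalidates steps inside turning intervals and
#' builds the binary label channels.
#'
#' @param fs a `feature_set` from [build_feature_set()].
#' @param cfg a [labeler_config()].
#' @return A list with `steps` (data frame: `fo`, `mids`, `fc`, `step_type`,
#'   `valid`, `side`), `events` (a [gait_events()] table), `turning`
#'   (interval data frame) and `labels` (a `labeled_series`).
#' @export
label_gait <- function(fs, cfg = labeler_config()) {
  stopifnot(inherits(fs, "feature_set"))
  fsr <- fs$sampling_rate_hz
  mids <- detect_mids(fs$ang_vel_mag, cfg, fsr)
  steps <- detect_fo_fc(fs$ang_vel_mag, mids, cfg, fsr)
  steps <- classify_step_type(steps, cfg, fsr)
  turning <- detect_turning(fs$rot_mat_mag, cfg, fsr)
  steps <- validate_steps(steps, turning)
  steps$side <- if (nrow(steps)) fs$side else character(0)
  events <- steps_to_events(steps)
  labels <- make_label_channels(steps, fs$n_frames)
  list(steps = steps, events = events, turning = turning, labels = labels)
}

#' Expand a step table into an event table
#'
#' @param steps step data frame with `fo`, `mids`, `fc`, `valid`, `side`.
#' @return A [gait_events()] data frame sorted by frame.
#' @export
steps_to_events <- function(steps) {
  if (nrow(steps) == 0L) return(gait_events())
  ev <- gait_events(
    frame = c(steps$fo, steps$mids, steps$fc),
    phase = rep(c("FO", "MidS", "FC"), each = nrow(steps)),
    side = rep(steps$side, 3),
    valid = rep(steps$valid, 3))
  ev[order(ev$frame), , drop = FALSE]
}
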