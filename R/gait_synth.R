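#' Synthetic-gait configuration
#'
#' Describes a bilateral over-ground walking recording emulating the study
#' protocol: straight bouts at several self-selected speeds, 180-degree turns
#' with small steps between bouts, optional in-place stepping, and rests
#' between activities. Each step contributes the characteristic triple-peak
#' shape to the angular-velocity magnitude -- two short negative sagittal
#' gyroscope pulses when the foot leaves (foot-off) and strikes (foot-contact)
#' the ground, flanking one broad positive swing pulse (mid-swing). The
#' foot-off-to-mid-swing and mid-swing-to-foot-contact latencies are held
#' fixed across speed (swing time varies little with walking speed; cadence
#' changes act on the stance phase).
#'
#' Step-type morphology: steady steps use foot-off/mid-swing/foot-contact
#' peak amplitudes of 250/400/230 deg/s; the first step of a bout starts from
#' standing, so its foot-off amplitude is reduced to 70% of steady; the last
#' step ends in standing, so its foot-contact amplitude drops to 30% of
#' steady (its hardest-to-detect feature).
#'
#' @param seed integer seed; the same config + seed is bit-reproducible.
#' @param sampling_rate_hz sampling rate, default 100 Hz.
#' @param n_steps_per_bout steps per leg per straight bout, default 8.
#' @param cadence_steps_per_s per-leg step rate of each bout (one value per
#'   bout); default `c(0.9, 0.65, 1.15)` -- convenient, slow and fast paces.
#' @param step_templates named list of amplitude triples (deg/s) for
#'   `initial`, `steady`, `terminal` step types.
#' @param fo_to_mids_s,mids_to_fc_s within-step latencies, default 0.30/0.35 s.
#' @param noise_sd list of channel noise standard deviations:
#'   `gyr` (deg/s), `acc` (m/s^2), `rot` (dimensionless).
#' @param rest_gap_s rest between a bout and the adjacent turn, default 2.5 s
#'   (all step-classification gaps in the labeler assume at least 2 s).
#' @param pad_s standing time at the start and end, default 3 s.
#' @param turn_duration_s duration of each between-bout turn, default 2 s.
#' @param turn_angle_deg heading change per turn, default 180.
#' @param turn_steps if `TRUE` (default) small steps (amplitudes scaled by
#'   `turn_step_scale`, cadence 1.2/s) are taken while turning; their truth
#'   events are marked invalid.
#' @param turn_step_scale amplitude scale of turning steps, default 0.6.
#' @param in_place_segments optional list of `list(after_bout =, n_steps =)`
#'   entries adding in-place stepping (no heading change, no forward
#'   acceleration bursts) after the given bout; truth events marked invalid.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, sampling_rate_hz = 100,
                         n_steps_per_bout = 8,
                         cadence_steps_per_s = c(0.9, 0.65, 1.15),
                         step_templates = list(
                           initial = c(fo = 175, mids = 400, fc = 230),
                           steady = c(fo = 250, mids = 400, fc = 230),
                           terminal = c(fo = 250, mids = 400, fc = 69)),
                         fo_to_mids_s = 0.30, mids_to_fc_s = 0.35,
                         noise_sd = list(gyr = 10, acc = 0.3, rot = 0.005),
                         rest_gap_s = 2.5, pad_s = 3,
                         turn_duration_s = 2, turn_angle_deg = 180,
                         turn_steps = TRUE, turn_step_scale = 0.6,
                         in_place_segments = NULL) {
  stopifnot(sampling_rate_hz > 0, n_steps_per_bout >= 1,
            all(cadence_steps_per_s > 0), rest_gap_s > 0, pad_s > 0,
            turn_duration_s > 0)
  for (tp in c("initial", "steady", "terminal"))
    if (is.null(step_templates[[tp]])) stop("missing step template: ", tp)
  st <- step_templates$steady
  if (st["mids"] <= st["fo"] || st["mids"] <= st["fc"])
    stop("steady mid-swing amplitude must exceed both flank amplitudes")
  tt <- step_templates$terminal
  if (tt["fc"] >= min(tt["fo"], tt["mids"]))
    stop("terminal foot-contact amplitude must be the smallest of its triple")
  swing <- fo_to_mids_s + mids_to_fc_s
  if (any(1 / cadence_steps_per_s <= swing + 0.05))
    stop(sprintf("steps overlap: cadence above %.2f steps/s leaves no stance time",
                 1 / (swing + 0.05)))
  structure(list(seed = as.integer(seed), sampling_rate_hz = sampling_rate_hz,
                 n_steps_per_bout = as.integer(n_steps_per_bout),
                 cadence_steps_per_s = cadence_steps_per_s,
                 step_templates = step_templates,
                 fo_to_mids_s = fo_to_mids_s, mids_to_fc_s = mids_to_fc_s,
                 noise_sd = noise_sd, rest_gap_s = rest_gap_s, pad_s = pad_s,
                 turn_duration_s = turn_duration_s,
                 turn_angle_deg = turn_angle_deg,
                 turn_steps = isTRUE(turn_steps),
                 turn_step_scale = turn_step_scale,
                 in_place_segments = in_place_segments),
            class = "synth_config")
}

gauss_pulse <- function(n, fs, center_s, amp, sd_s) {
  c_fr <- center_s * fs
  sd_fr <- sd_s * fs
  lo <- max(1L, floor(c_fr - 5 * sd_fr))
  hi <- min(n, ceiling(c_fr + 5 * sd_fr))
  idx <- lo:hi
  vals <- amp * exp(-((idx - 1 - c_fr)^2) / (2 * sd_fr^2))
  list(idx = idx, vals = vals)
}

add_pulse <- function(x, fs, center_s, amp, sd_s) {
  p <- gauss_pulse(length(x), fs, center_s, amp, sd_s)
  x[p$idx] <- x[p$idx] + p$vals
  x
}

#' Simulate a bilateral walking recording with ground truth
#'
#' Lays out the protocol timeline described by the config (standing pad,
#' straight bouts at the configured cadences, turns with small invalid steps
#' between bouts, optional in-place stepping), synthesizes the seven raw
#' channels per leg and returns the exact ground-truth event frames. The
#' sagittal gyroscope (`Gyr_Z`) carries two negative pulses (toe-off and
#' heel-strike surrogates, sd 0.04 s) flanking one positive swing pulse
#' (sd 0.08 s) per step, so the angular-velocity magnitude shows the
#' triple-peak step shape; free-acceleration bursts coincide with foot-off
#' and foot-contact; the `Mat[1][1]` direction cosine follows `cos(heading)`,
#' constant during straight bouts and sweeping during turns. Legs alternate
#' with a half-cycle phase offset. Gaussian noise is added per channel.
#'
#' @param cfg a [synth_config()].
#' @return List with `paired` (a `paired_recording` of raw channels), `truth`
#'   (a [gait_events()] table for both legs, turning/in-place steps marked
#'   invalid), `steps` (per-step truth with `step_type`), `turning_truth`
#'   (data frame of turning intervals, 0-based frames) and `config`.
#' @export
synth_walk <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$sampling_rate_hz
  n_bouts <- length(cfg$cadence_steps_per_s)

  # ---- timeline ----
  steps <- list()   # side, t_fo, type, in_turn, in_place
  turns <- list()   # start_s, end_s
  add_step <- function(side, t_fo, type, in_turn = FALSE, in_place = FALSE,
                       scale = 1) {
    steps[[length(steps) + 1L]] <<- list(side = side, t_fo = t_fo,
                                         type = type, in_turn = in_turn,
                                         in_place = in_place, scale = scale)
  }
  t_cur <- cfg$pad_s
  heading_segments <- list()  # list(start, end, from, to) in radians
  heading <- 0
  for (b in seq_len(n_bouts)) {
    period <- 1 / cfg$cadence_steps_per_s[b]
    nst <- cfg$n_steps_per_bout
    for (k in seq_len(nst)) {
      type <- if (nst == 1L || k == nst) "terminal"
              else if (k == 1L) "initial" else "steady"
      for (side in c("left", "right")) {
        off <- if (side == "left") 0 else period / 2
        add_step(side, t_cur + (k - 1) * period + off, type)
      }
    }
    bout_dur <- (nst - 1) * period + period / 2 + cfg$mids_to_fc_s +
      cfg$fo_to_mids_s
    t_cur <- t_cur + bout_dur
    # optional in-place stepping after this bout
    for (seg in cfg$in_place_segments %||% list()) {
      if (seg$after_bout != b) next
      t_cur <- t_cur + cfg$rest_gap_s
      ip_period <- 1 / 1.0
      for (k in seq_len(seg$n_steps)) for (side in c("left", "right")) {
        off <- if (side == "left") 0 else ip_period / 2
        add_step(side, t_cur + (k - 1) * ip_period + off, "steady",
                 in_place = TRUE, scale = 0.7)
      }
      t_cur <- t_cur + seg$n_steps * ip_period
    }
    if (b < n_bouts) {
      t_cur <- t_cur + cfg$rest_gap_s
      turn_start <- t_cur
      turn_end <- t_cur + cfg$turn_duration_s
      turns[[length(turns) + 1L]] <- c(turn_start, turn_end)
      heading_segments[[length(heading_segments) + 1L]] <-
        list(start = turn_start, end = turn_end, from = heading,
             to = heading + cfg$turn_angle_deg * pi / 180)
      heading <- heading + cfg$turn_angle_deg * pi / 180
      if (cfg$turn_steps) {
        ts_period <- 1 / 1.2
        k <- 0L
        repeat {
          t0 <- turn_start + k * ts_period
          if (t0 + cfg$fo_to_mids_s + cfg$mids_to_fc_s > turn_end) break
          add_step("left", t0, "steady", in_turn = TRUE,
                   scale = cfg$turn_step_scale)
          t0r <- t0 + ts_period / 2
          if (t0r + cfg$fo_to_mids_s + cfg$mids_to_fc_s <= turn_end)
            add_step("right", t0r, "steady", in_turn = TRUE,
                     scale = cfg$turn_step_scale)
          k <- k + 1L
        }
      }
      t_cur <- turn_end + cfg$rest_gap_s
    }
  }
  total_s <- t_cur + cfg$pad_s
  n <- ceiling(total_s * fs)
  tvec <- (0:(n - 1)) / fs

  # heading profile -> Mat[1][1] of both legs
  hvec <- numeric(n)
  for (seg in heading_segments) {
    ramp <- tvec >= seg$start & tvec <= seg$end
    hvec[ramp] <- seg$from + (seg$to - seg$from) *
      (tvec[ramp] - seg$start) / (seg$end - seg$start)
    hvec[tvec > seg$end] <- seg$to
  }

  # per-leg channels
  mk_leg <- function(side) {
    gz <- numeric(n); az <- numeric(n)
    for (s in steps) {
      if (s$side != side) next
      amp <- cfg$step_templates[[s$type]] * s$scale
      t_fo <- s$t_fo
      t_mids <- t_fo + cfg$fo_to_mids_s
      t_fc <- t_mids + cfg$mids_to_fc_s
      gz <- add_pulse(gz, fs, t_fo, -amp[["fo"]], 0.04)
      gz <- add_pulse(gz, fs, t_mids, amp[["mids"]], 0.08)
      gz <- add_pulse(gz, fs, t_fc, -amp[["fc"]], 0.04)
      if (!s$in_place) {
        az <- add_pulse(az, fs, t_fo, 3, 0.03)
        az <- add_pulse(az, fs, t_fc, 3, 0.03)
        az <- add_pulse(az, fs, t_mids, 1, 0.05)
      }
    }
    list(gz = gz, az = az)
  }
  left_sig <- mk_leg("left")
  right_sig <- mk_leg("right")

  rec <- with_seed(cfg$seed, {
    noise <- cfg$noise_sd
    mk_rec <- function(sig, side) {
      gyr <- cbind(stats::rnorm(n, 0, noise$gyr),
                   stats::rnorm(n, 0, noise$gyr),
                   sig$gz + stats::rnorm(n, 0, noise$gyr))
      acc <- cbind(stats::rnorm(n, 0, noise$acc),
                   stats::rnorm(n, 0, noise$acc),
                   sig$az + stats::rnorm(n, 0, noise$acc))
      r11 <- cos(hvec) + stats::rnorm(n, 0, noise$rot)
      imu_recording(gyr, acc, r11, side, fs)
    }
    list(left = mk_rec(left_sig, "left"), right = mk_rec(right_sig, "right"))
  })
  paired <- pair_recordings(rec$left, rec$right)

  # truth tables
  step_rows <- lapply(steps, function(s) {
    t_fo <- s$t_fo
    data.frame(side = s$side,
               fo = round(t_fo * fs),
               mids = round((t_fo + cfg$fo_to_mids_s) * fs),
               fc = round((t_fo + cfg$fo_to_mids_s + cfg$mids_to_fc_s) * fs),
               step_type = s$type,
               valid = !(s$in_turn || s$in_place))
  })
  steps_df <- do.call(rbind, step_rows)
  steps_df <- steps_df[order(steps_df$fo), , drop = FALSE]
  truth <- steps_to_events(steps_df)
  turning_truth <- if (length(turns)) {
    data.frame(start = vapply(turns, function(x) round(x[1] * fs), double(1)),
               end = vapply(turns, function(x) round(x[2] * fs), double(1)))
  } else data.frame(start = integer(0), end = integer(0))
  list(paired = paired, truth = truth, steps = steps_df,
       turning_truth = turning_truth, config = cfg)
}

#' Truth-derived label channels for one leg of a simulation
#'
#' @param sim a [synth_walk()] result.
#' @param side `"left"` or `"right"`.
#' @return A `labeled_series` built from the valid truth events of that leg.
#' @export
truth_labels <- function(sim, side) {
  st <- sim$steps[sim$steps$side == side, , drop = FALSE]
  make_label_channels(st, sim$paired$left$n_frames)
}

#' Build a training window set from simulations
#'
#' Runs the forward half of the pipeline (cleaning, features, windowing) on
#' each simulated recording and attaches truth-derived targets -- not the
#' labeler's output -- so model training does not inherit labeler errors.
#' Both legs of each simulation are used as separate recordings, each
#' balanced individually before the tensors are concatenated. When
#' undersampling, half of the kept negatives are drawn from within
#' `hard_negative_window_frames` of any truth event of any phase, valid or
#' not: these hard negatives (other phases' peaks, near-misses, turning
#' steps) are what force the model to localize its own phase rather than
#' respond to any step peak.
#'
#' @param cfgs list of [synth_config()] objects.
#' @param phase `"FO"`, `"MidS"` or `"FC"`.
#' @param pre a [preprocess_config()].
#' @param L window length, default 251.
#' @param strategy,ratio,dilation_frames,seed balancing, see
#'   [balance_windows()]; default undersampling with target dilation.
#' @param hard_negative_window_frames half-width of the hard-negative band
#'   around truth events, default 170 frames -- wide enough to cover the
#'   whole adjacent gait cycle at every simulated cadence, where
#'   one-cycle-shifted false positives arise.
#' @return List with `combined` (balanced `window_tensor` over all
#'   recordings) and `per_recording` (named list of the per-recording
#'   tensors, balanced unless `strategy = "none"`).
#' @export
synth_training_set <- function(cfgs, phase, pre = preprocess_config(),
                               L = 251, strategy = "target_dilation",
                               ratio = 3, dilation_frames = 2, seed = 1,
                               hard_negative_window_frames = 170) {
  per <- list()
  for (ci in seq_along(cfgs)) {
    sim <- synth_walk(cfgs[[ci]])
    cleaned <- clean_recording(sim$paired, pre)
    for (side in c("left", "right")) {
      fs <- build_feature_set(cleaned, side, pre)
      wt <- make_windows(fs, truth_labels(sim, side), phase, L)
      if (strategy != "none") {
        ev <- sim$steps[sim$steps$side == side, , drop = FALSE]
        ev_frames <- c(ev$fo, ev$mids, ev$fc)
        hard <- unique(unlist(lapply(ev_frames, function(e)
          (e - hard_negative_window_frames):(e + hard_negative_window_frames))))
        wt <- balance_windows(wt, strategy, ratio = ratio,
                              dilation_frames = dilation_frames,
                              seed = seed + ci, hard_frames = hard,
                              hard_frac = 0.6)
      }
      per[[sprintf("sim%d_%s", ci, side)]] <- wt
    }
  }
  list(combined = combine_window_tensors(per), per_recording = per)
}
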