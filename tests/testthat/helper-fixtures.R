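# shared fixtures: all synthetic, built in code at test time

# a short single-bout protocol (fast to simulate and label)
tiny_synth_config <- function(seed = 1, n_steps = 6, cadence = 0.9, ...) {
  synth_config(seed = seed, n_steps_per_bout = n_steps,
               cadence_steps_per_s = cadence, ...)
}

# random imu_recording with well-behaved channels
random_recording <- function(n = 50, side = "left", seed = 1) {
  with_seed <- getFromNamespace("with_seed", "gaitphase")
  with_seed(seed, {
    imu_recording(gyr = matrix(stats::rnorm(n * 3, 0, 50), ncol = 3),
                  free_acc = matrix(stats::rnorm(n * 3, 0, 2), ncol = 3),
                  rot_mat_11 = stats::runif(n, -1, 1),
                  side = side)
  })
}

# feature_set wrapper around explicit channel vectors
manual_feature_set <- function(avm, fam = NULL, rmm = NULL, side = "left",
                               fs_hz = 100) {
  n <- length(avm)
  structure(list(side = side,
                 ang_vel_mag = avm,
                 free_acc_mag = fam %||% rep(0.5, n),
                 rot_mat_mag = rmm %||% rep(sqrt(2), n),
                 ang_vel_mag_raw = avm,
                 n_frames = n, sampling_rate_hz = fs_hz),
            class = "feature_set")
}

manual_trace <- function(p, first_center = 125, phase = "MidS", fs_hz = 100) {
  structure(list(phase = phase, probabilities = p,
                 frames = first_center + seq_along(p) - 1L,
                 first_center_frame = first_center,
                 sampling_rate_hz = fs_hz),
            class = "prediction_trace")
}

manual_labels <- function(fo, mids, fc, n) {
  mk <- function(fr) { ch <- integer(n); ch[fr + 1L] <- 1L; ch }
  structure(list(fo = mk(fo), mids = mk(mids), fc = mk(fc), n_frames = n),
            class = "labeled_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# distance from each truth frame to the nearest labeled frame
nearest_dist <- function(truth_frames, labeled_frames) {
  vapply(truth_frames, function(f) {
    if (!length(labeled_frames)) return(Inf)
    min(abs(labeled_frames - f))
  }, numeric(1))
}

# exhaustive maximum-cardinality one-to-one matcher (oracle for the greedy
# matcher): recursion over truth events, each matched to any unused
# prediction within tolerance or skipped
optimal_match_count <- function(truth, pred, tol) {
  nt <- length(truth)
  np <- length(pred)
  best <- 0L
  recurse <- function(ti, used, count) {
    if (count + (nt - ti + 1L) <= best) return()
    if (ti > nt) { best <<- max(best, count); return() }
    recurse(ti + 1L, used, count)  # skip this truth event
    for (pj in seq_len(np)) {
      if (!used[pj] && abs(truth[ti] - pred[pj]) <= tol) {
        used[pj] <- TRUE
        recurse(ti + 1L, used, count + 1L)
        used[pj] <- FALSE
      }
    }
  }
  recurse(1L, logical(np), 0L)
  best
}
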