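#' Assemble a full run configuration
#'
#' Bundles every stage configuration plus the global seed, with two presets:
#' `"paper_fidelity"` (full model size, 100 epochs, learning rate 1e-4,
#' unbalanced windows -- the original training regime) and `"desk_scale"`
#' (units 8/16/16/16/8, 10 epochs, learning rate 1e-3, dilated + undersampled
#' windows -- trains per phase in minutes on one CPU). All resolved values are
#' written into the run-metadata file of every run, because none of the
#' detection/training constants are standardized and provenance is the only
#' way to compare runs.
#'
#' @param profile `"desk_scale"` or `"paper_fidelity"`.
#' @param seed global seed; stage seeds are derived from it.
#' @param preprocess,labeler,model,train,caller,balance stage overrides.
#' @return A list of class `run_config`.
#' @export
run_config <- function(profile = c("desk_scale", "paper_fidelity"), seed = 1,
                       preprocess = preprocess_config(),
                       labeler = labeler_config(),
                       model = NULL, train = NULL,
                       caller = caller_config(),
                       balance = NULL) {
  profile <- match.arg(profile)
  if (is.null(model)) model <- model_spec(profile = profile)
  if (is.null(train)) train <- train_config(profile = profile, seed = seed)
  if (is.null(balance)) {
    balance <- if (profile == "desk_scale")
      list(strategy = "target_dilation", ratio = 6, dilation_frames = 2)
    else list(strategy = "none", ratio = NA, dilation_frames = NA)
  }
  structure(list(profile = profile, seed = as.integer(seed),
                 preprocess = preprocess, labeler = labeler, model = model,
                 train = train, caller = caller, balance = balance),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file may contain any of the sections `preprocess`, `labeler`, `model`,
#' `train`, `caller`, `balance` plus top-level `profile` and `seed`; each
#' section holds overrides for the corresponding configuration constructor
#' (e.g. `preprocess: {smoothing_fwhm_frames: 9, acc_valid_range: 160}`).
#' Anything omitted takes the profile's defaults.
#'
#' @param path YAML file path.
#' @param profile,seed defaults when the file does not set them.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, profile = "desk_scale", seed = 1) {
  y <- yaml::read_yaml(path) %||% list()
  profile <- y$profile %||% profile
  seed <- y$seed %||% seed
  build <- function(ctor, overrides, ...) do.call(ctor, c(overrides %||% list(), ...))
  cfg <- run_config(
    profile = profile, seed = seed,
    preprocess = build(preprocess_config, y$preprocess),
    labeler = build(labeler_config, y$labeler),
    caller = build(caller_config, y$caller))
  if (!is.null(y$model))
    cfg$model <- do.call(model_spec,
                         utils::modifyList(unclass(cfg$model), y$model))
  if (!is.null(y$train))
    cfg$train <- do.call(train_config,
                         utils::modifyList(unclass(cfg$train), y$train))
  if (!is.null(y$balance)) cfg$balance <- utils::modifyList(cfg$balance, y$balance)
  cfg
}

run_metadata <- function(cfg, extra = list()) {
  c(list(package_version = as.character(utils::packageVersion("gaitphase")),
         profile = cfg$profile, seed = cfg$seed,
         preprocess = unclass(cfg$preprocess),
         labeler = unclass(cfg$labeler),
         model = unclass(cfg$model),
         train = unclass(cfg$train),
         caller = unclass(cfg$caller),
         balance = cfg$balance),
    extra)
}

write_metadata <- function(meta, path)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)

#' Label a bilateral recording end to end
#'
#' Runs cleaning, feature extraction and the peak-based labeler for both
#' legs. With `out_dir` set, writes per-leg event tables, label-channel CSVs
#' and a run-metadata JSON capturing every resolved parameter before any
#' output is computed.
#'
#' @param paired a `paired_recording` (raw channels).
#' @param cfg a [run_config()].
#' @param out_dir optional output directory.
#' @return Named list (`left`, `right`) of [label_gait()] results, plus
#'   `features` (per-leg `feature_set`s) and `metadata`.
#' @export
run_label <- function(paired, cfg = run_config(), out_dir = NULL) {
  stopifnot(inherits(paired, "paired_recording"))
  meta <- run_metadata(cfg, list(stage = "label",
                                 n_frames = paired$left$n_frames))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metadata(meta, file.path(out_dir, "run_metadata.json"))
  }
  cleaned <- clean_recording(paired, cfg$preprocess)
  out <- list(features = list(), metadata = meta)
  for (side in c("left", "right")) {
    fs <- build_feature_set(cleaned, side, cfg$preprocess)
    res <- label_gait(fs, cfg$labeler)
    out$features[[side]] <- fs
    out[[side]] <- res
    if (!is.null(out_dir)) {
      write_events(res$events, file.path(out_dir, paste0("events_", side, ".csv")),
                   fs$sampling_rate_hz)
      utils::write.csv(
        data.frame(frame = seq_len(fs$n_frames) - 1L,
                   label_fo = res$labels$fo, label_mids = res$labels$mids,
                   label_fc = res$labels$fc),
        file.path(out_dir, paste0("labels_", side, ".csv")), row.names = FALSE)
    }
  }
  out
}

#' Train per-phase models on simulations and evaluate on held-out ones
#'
#' For each phase, builds a truth-labeled, balanced window set from the
#' training simulations, trains the recurrent model, then runs the
#' probability trace + event caller over each held-out recording and scores
#' frame-level metrics (including the all-negative baseline accuracy) and
#' event-level precision/recall/F1 against the ground truth.
#'
#' @param train_cfgs list of [synth_config()]s for training recordings.
#' @param test_cfgs list of [synth_config()]s for held-out recordings.
#' @param cfg a [run_config()].
#' @param phases phases to train, default all three.
#' @param tolerance_frames event-matching tolerance, default 5 (50 ms).
#' @param out_dir optional output directory for metadata, histories, metrics.
#' @return List with per-phase entries (`model`, `frame` metrics per test
#'   recording, `events` metrics per test recording, `pooled` event metrics)
#'   and `metadata`.
#' @export
run_train_eval <- function(train_cfgs, test_cfgs, cfg = run_config(),
                           phases = c("FO", "MidS", "FC"),
                           tolerance_frames = 5, out_dir = NULL) {
  meta <- run_metadata(cfg, list(
    stage = "train_eval",
    n_train_recordings = length(train_cfgs),
    n_test_recordings = length(test_cfgs),
    train_seeds = vapply(train_cfgs, function(s) s$seed, integer(1)),
    test_seeds = vapply(test_cfgs, function(s) s$seed, integer(1)),
    tolerance_frames = tolerance_frames))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_metadata(meta, file.path(out_dir, "run_metadata.json"))
  }

  # held-out recordings: features + truth, computed once
  tests <- lapply(test_cfgs, function(sc) {
    sim <- synth_walk(sc)
    cleaned <- clean_recording(sim$paired, cfg$preprocess)
    list(sim = sim,
         features = list(left = build_feature_set(cleaned, "left", cfg$preprocess),
                         right = build_feature_set(cleaned, "right", cfg$preprocess)))
  })

  out <- list(metadata = meta)
  for (phase in phases) {
    ts <- synth_training_set(train_cfgs, phase, cfg$preprocess,
                             L = cfg$model$seq_len,
                             strategy = cfg$balance$strategy,
                             ratio = cfg$balance$ratio,
                             dilation_frames = cfg$balance$dilation_frames,
                             seed = cfg$seed)
    model <- build_model(cfg$model, seed = cfg$seed)
    model <- train_phase_model(model, ts$combined, val = NULL, cfg$train)
    frame_rows <- list(); event_rows <- list()
    pooled_pred <- pooled_truth <- 0L
    pooled_matched <- 0L; pooled_err <- numeric(0)
    for (ti in seq_along(tests)) {
      te <- tests[[ti]]
      for (side in c("left", "right")) {
        fs <- te$features[[side]]
        trace <- predict_trace(model, fs)
        labels <- truth_labels(te$sim, side)
        fm <- frame_metrics(trace, labels, phase)
        called <- call_events(trace, cfg$caller, side)
        called <- refine_on_signal(called, fs$ang_vel_mag_raw, cfg$caller,
                                   fs$sampling_rate_hz)
        st <- te$sim$steps
        tru <- st[st$side == side & st$valid, , drop = FALSE]
        truth_ev <- data.frame(frame = tru[[tolower_phase(phase)]])
        em <- evaluate_events(called, truth_ev, tolerance_frames)
        key <- sprintf("test%d_%s", ti, side)
        frame_rows[[key]] <- data.frame(
          recording = key, phase = phase, accuracy = fm$accuracy,
          bce_loss = fm$bce_loss, baseline_accuracy = fm$baseline_accuracy)
        event_rows[[key]] <- data.frame(
          recording = key, phase = phase, precision = em$precision,
          recall = em$recall, f1 = em$f1,
          mean_abs_timing_error_frames = em$mean_abs_timing_error_frames,
          n_predicted = nrow(called), n_truth = nrow(truth_ev))
        pooled_pred <- pooled_pred + nrow(called)
        pooled_truth <- pooled_truth + nrow(truth_ev)
        pooled_matched <- pooled_matched + em$n_matched
        if (em$n_matched)
          pooled_err <- c(pooled_err, abs(em$matches$truth_frame -
                                            em$matches$predicted_frame))
      }
    }
    prec <- if (pooled_pred) pooled_matched / pooled_pred else 1
    rec <- if (pooled_truth) pooled_matched / pooled_truth else 1
    out[[phase]] <- list(
      model = model,
      frame = do.call(rbind, frame_rows),
      events = do.call(rbind, event_rows),
      pooled = list(precision = prec, recall = rec,
                    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
                    mean_abs_timing_error_frames =
                      if (length(pooled_err)) mean(pooled_err) else NA_real_))
    if (!is.null(out_dir)) {
      utils::write.csv(model$history,
                       file.path(out_dir, paste0("history_", phase, ".csv")),
                       row.names = FALSE)
      utils::write.csv(out[[phase]]$events,
                       file.path(out_dir, paste0("event_metrics_", phase, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}

tolower_phase <- function(phase)
  switch(phase, FO = "fo", MidS = "mids", FC = "fc",
         stop("unknown phase: ", phase))
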