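#' Architecture of a per-phase sequence model
#'
#' One recurrent (LSTM) model is trained per gait phase. The layer sequence is
#' LSTM(input_units) -> 3 x LSTM(hidden) -> LSTM(final_recurrent_units) ->
#' Dense(1, sigmoid), every recurrent layer followed by batch normalization
#' and dropout; all recurrent layers except the last return per-step
#' sequences, the last returns its final state. The default sizes
#' (30, 60, 60, 60, 30) are the full profile; `profile = "desk_scale"` swaps
#' in (8, 16, 16, 16, 8), small enough to train on a single CPU in minutes.
#'
#' @param input_units units of the first recurrent layer (default 30).
#' @param hidden_units integer vector of hidden recurrent layer sizes
#'   (default `c(60, 60, 60)`).
#' @param final_recurrent_units units of the last recurrent layer (default 30).
#' @param dropout_rate dropout rate in `[0, 1)`, default 0.2.
#' @param batch_norm_momentum running-statistics momentum, default 0.99.
#' @param batch_norm_epsilon variance floor, default 0.001.
#' @param seq_len window length, odd, default 251.
#' @param n_features input channels, default 3.
#' @param profile `NULL` or `"desk_scale"` / `"paper_fidelity"`.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(input_units = 30, hidden_units = c(60, 60, 60),
                       final_recurrent_units = 30, dropout_rate = 0.2,
                       batch_norm_momentum = 0.99,
                       batch_norm_epsilon = 0.001,
                       seq_len = 251, n_features = 3, profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("paper_fidelity", "desk_scale"))
    if (profile == "desk_scale") {
      input_units <- 8; hidden_units <- c(16, 16, 16)
      final_recurrent_units <- 8
    }
  }
  units <- c(input_units, hidden_units, final_recurrent_units)
  if (any(units <= 0) || any(units != round(units)))
    stop("all unit counts must be positive integers")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (seq_len %% 2 == 0) stop("seq_len must be odd")
  structure(list(input_units = input_units, hidden_units = hidden_units,
                 final_recurrent_units = final_recurrent_units,
                 dropout_rate = dropout_rate,
                 batch_norm_momentum = batch_norm_momentum,
                 batch_norm_epsilon = batch_norm_epsilon,
                 seq_len = as.integer(seq_len),
                 n_features = as.integer(n_features)),
            class = "model_spec")
}

spec_units <- function(spec)
  as.integer(c(spec$input_units, spec$hidden_units, spec$final_recurrent_units))

#' Number of trainable parameters of a [model_spec()]
#' @param spec a `model_spec`.
#' @return Integer parameter count.
#' @export
param_count <- function(spec) {
  units <- spec_units(spec)
  din <- spec$n_features
  n <- 0L
  for (u in units) {
    n <- n + 4L * u * din + 4L * u * u + 4L * u + 2L * u
    din <- u
  }
  n + units[length(units)] + 1L
}

#' Training configuration
#'
#' Adam on binary cross-entropy. The full profile uses learning rate 1e-4 and
#' 100 epochs; `"desk_scale"` uses 1e-3, 10 epochs and batch 32, sized for
#' CPU training on balanced synthetic windows.
#'
#' @param learning_rate Adam learning rate, default 1e-4.
#' @param epochs training epochs, default 100.
#' @param batch_size minibatch size; no standardized value exists, default 64
#'   (logged in run metadata).
#' @param seed integer seed governing weight init order, shuffling and dropout.
#' @param beta1,beta2,adam_epsilon Adam moment parameters.
#' @param profile `NULL` or `"desk_scale"` / `"paper_fidelity"`.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 100, batch_size = 64,
                         seed = 1, beta1 = 0.9, beta2 = 0.999,
                         adam_epsilon = 1e-8, profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("paper_fidelity", "desk_scale"))
    if (profile == "desk_scale") {
      learning_rate <- 1e-3; epochs <- 10; batch_size <- 32
    }
  }
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, adam_epsilon = adam_epsilon),
            class = "train_config")
}

#' Build an untrained per-phase model
#'
#' Initializes all weights (uniform Glorot for input and recurrent kernels,
#' forget-gate bias 2 for long initial memory, batch-norm gamma 1 / beta 0)
#' and the batch-norm running
#' statistics. Initialization is reproducible from `seed`.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `phase_model` with fields `spec`, `params`,
#'   `state` (batch-norm running stats), `history`, `phase`, `scaling`.
#' @export
build_model <- function(spec = model_spec(), seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  units <- spec_units(spec)
  params <- with_seed(seed, {
    out <- numeric(0)
    din <- spec$n_features
    for (u in units) {
      lim_x <- sqrt(6 / (din + 4 * u))
      lim_h <- sqrt(6 / (u + 4 * u))
      b <- rep(0, 4 * u)
      b[(u + 1):(2 * u)] <- 2  # forget-gate bias: long memory at init
      out <- c(out,
               stats::runif(4 * u * din, -lim_x, lim_x),
               stats::runif(4 * u * u, -lim_h, lim_h),
               b, rep(1, u), rep(0, u))
      din <- u
    }
    lim_d <- sqrt(6 / (din + 1))
    c(out, stats::runif(din, -lim_d, lim_d), 0)
  })
  state <- unlist(lapply(units, function(u) c(rep(0, u), rep(1, u))))
  structure(list(spec = spec, params = params, state = state,
                 history = NULL, phase = NULL, trained_epochs = 0L,
                 scaling = "per_recording_minmax", seed = as.integer(seed)),
            class = "phase_model")
}

#' @export
print.phase_model <- function(x, ...) {
  cat(sprintf("<phase_model> phase=%s, units [%s], %d params, %d epoch(s) trained\n",
              x$phase %||% "?", paste(spec_units(x$spec), collapse = ", "),
              param_count(x$spec), x$trained_epochs))
  invisible(x)
}

# (C, N, L) cube expected by the compiled core
windows_to_cube <- function(arr) aperm(arr, c(3, 1, 2))

model_forward <- function(model, cube, y = numeric(0), training = FALSE,
                          compute_grad = FALSE) {
  spec <- model$spec
  lstm_stack_run(model$params, cube, y, spec_units(spec), spec$dropout_rate,
                 spec$batch_norm_momentum, spec$batch_norm_epsilon,
                 model$state, training, compute_grad)
}

#' Train a per-phase model
#'
#' Minibatch Adam on binary cross-entropy. Each epoch reshuffles the windows
#' (seeded), runs forward/backward through the compiled recurrent stack
#' (dropout active, batch statistics), applies Adam updates, and then scores
#' the validation tensor in inference mode (dropout off, running batch-norm
#' statistics). With `cfg$epochs = 0` the initialized model is returned
#' unchanged. Training is bit-reproducible for a fixed seed, data and config.
#'
#' @param model a [build_model()] result.
#' @param windows training `window_tensor` (typically balanced, see
#'   [balance_windows()]).
#' @param val optional validation `window_tensor`.
#' @param cfg a [train_config()].
#' @return The trained `phase_model`; `$history` holds one row per epoch with
#'   `loss`, `accuracy`, `val_loss`, `val_accuracy`.
#' @export
train_phase_model <- function(model, windows, val = NULL,
                              cfg = train_config()) {
  stopifnot(inherits(model, "phase_model"), inherits(windows, "window_tensor"))
  spec <- model$spec
  if (windows$L != spec$seq_len || dim(windows$windows)[3] != spec$n_features)
    stop(sprintf("window shape (%d, %d) does not match model spec (%d, %d)",
                 windows$L, dim(windows$windows)[3],
                 spec$seq_len, spec$n_features))
  model$phase <- windows$phase
  if (cfg$epochs == 0L) { model$history <- empty_history(); return(model) }

  x <- windows_to_cube(windows$windows)
  y <- as.numeric(windows$targets)
  n <- length(y)
  m_adam <- v_adam <- numeric(length(model$params))
  step <- 0L
  hist <- vector("list", cfg$epochs)

  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        res <- model_forward(model, x[, idx, , drop = FALSE], y[idx],
                             training = TRUE, compute_grad = TRUE)
        model$state <- res$state
        g <- res$grad
        step <- step + 1L
        m_adam <- cfg$beta1 * m_adam + (1 - cfg$beta1) * g
        v_adam <- cfg$beta2 * v_adam + (1 - cfg$beta2) * g^2
        mhat <- m_adam / (1 - cfg$beta1^step)
        vhat <- v_adam / (1 - cfg$beta2^step)
        model$params <- model$params -
          cfg$learning_rate * mhat / (sqrt(vhat) + cfg$adam_epsilon)
        ep_loss <- ep_loss + res$loss * length(idx)
        ep_correct <- ep_correct + sum((res$probs > 0.5) == (y[idx] == 1))
      }
      vl <- va <- NA_real_
      if (!is.null(val)) {
        vres <- evaluate_windows(model, val)
        vl <- vres$bce_loss; va <- vres$accuracy
      }
      hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n,
                               accuracy = ep_correct / n,
                               val_loss = vl, val_accuracy = va)
    }
  })
  model$history <- do.call(rbind, hist)
  model$trained_epochs <- model$trained_epochs + cfg$epochs
  model$train_config <- cfg
  model
}

empty_history <- function()
  data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0),
             val_loss = numeric(0), val_accuracy = numeric(0))

#' Score a window tensor in inference mode
#'
#' @param model a trained `phase_model`.
#' @param windows a `window_tensor` with targets.
#' @param chunk maximum windows per forward pass (memory control).
#' @return List with `accuracy`, `bce_loss`, `probs`.
#' @export
evaluate_windows <- function(model, windows, chunk = 512L) {
  y <- as.numeric(windows$targets)
  p <- predict_window_probs(model, windows$windows, chunk = chunk)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  list(accuracy = mean((p > 0.5) == (y == 1)),
       bce_loss = -mean(y * log(pc) + (1 - y) * log(1 - pc)),
       probs = p)
}

predict_window_probs <- function(model, arr, chunk = 512L) {
  N <- dim(arr)[1]
  p <- numeric(N)
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    cube <- windows_to_cube(arr[idx, , , drop = FALSE])
    p[idx] <- model_forward(model, cube)$probs
  }
  p
}

#' Per-frame phase-probability trace over a recording
#'
#' Slides the model across every possible center frame of the feature series
#' (scaled per recording, as at training time) and returns the per-frame
#' probability that the phase occurs there: `n_frames - L + 1` values aligned
#' to frames `(L-1)/2 ... n_frames - (L+1)/2`.
#'
#' @param model a trained `phase_model`.
#' @param fs a `feature_set` of at least `seq_len` frames.
#' @param chunk windows per forward pass.
#' @return An object of class `prediction_trace`: list with `phase`,
#'   `probabilities`, `frames` (0-based center frames), `first_center_frame`,
#'   `sampling_rate_hz`.
#' @export
predict_trace <- function(model, fs, chunk = 512L) {
  stopifnot(inherits(model, "phase_model"), inherits(fs, "feature_set"))
  L <- model$spec$seq_len
  n <- fs$n_frames
  if (n < L)
    stop(sprintf("recording too short for prediction: %d < %d frames", n, L))
  Fm <- feature_matrix(fs, scale = TRUE)
  N <- n - L + 1L
  offset <- (L - 1L) %/% 2L
  p <- numeric(N)
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    cube <- array(NA_real_, dim = c(ncol(Fm), length(idx), L))
    for (t in seq_len(L)) cube[, , t] <- t(Fm[(idx[1] + t - 2L) + seq_along(idx), , drop = FALSE])
    p[idx] <- model_forward(model, cube)$probs
  }
  structure(list(phase = model$phase, probabilities = p,
                 frames = offset + 0:(N - 1L),
                 first_center_frame = offset,
                 sampling_rate_hz = fs$sampling_rate_hz),
            class = "prediction_trace")
}

#' @export
print.prediction_trace <- function(x, ...) {
  cat(sprintf("<prediction_trace> phase=%s, %d values over frames %d..%d\n",
              x$phase %||% "?", length(x$probabilities), x$frames[1],
              x$frames[length(x$frames)]))
  invisible(x)
}

#' Frame-level accuracy and cross-entropy of a trace
#'
#' Crops the label channel to the trace's frame range and scores the trace as
#' a per-frame binary classifier: accuracy of the thresholded probabilities
#' (p >= 0.5) against the labels, and mean binary cross-entropy with
#' probabilities clamped away from 0/1 by 1e-7. Because positive frames are
#' extremely rare, the all-negative baseline accuracy is reported alongside --
#' frame accuracy close to that baseline carries little information, which is
#' why event-level scores (see [evaluate_events()]) are the primary metric.
#'
#' @param trace a `prediction_trace`.
#' @param labels a `labeled_series` covering the recording.
#' @param phase `"FO"`, `"MidS"` or `"FC"`.
#' @return List with `accuracy`, `bce_loss`, `baseline_accuracy`.
#' @export
frame_metrics <- function(trace, labels, phase = trace$phase) {
  ch <- label_channel(labels, phase)
  if (max(trace$frames) + 1L > length(ch))
    stop("label channel shorter than the trace's frame range")
  yl <- ch[trace$frames + 1L]
  p <- trace$probabilities
  if (length(yl) != length(p)) stop("trace/label length mismatch")
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  list(accuracy = mean((p > 0.5) == (yl == 1)),
       bce_loss = -mean(yl * log(pc) + (1 - yl) * log(1 - pc)),
       baseline_accuracy = mean(yl == 0))
}

#' Persist a trained model as a directory artifact
#'
#' Writes weights plus a JSON metadata file (architecture, training config,
#' scaling convention, training history) so a run can be audited and reloaded.
#'
#' @param model a `phase_model`.
#' @param dir directory to create.
#' @return `dir`, invisibly.
#' @export
save_phase_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  saveRDS(model$state, file.path(dir, "bn_state.rds"))
  meta <- list(spec = unclass(model$spec), phase = model$phase,
               scaling = model$scaling, seed = model$seed,
               trained_epochs = model$trained_epochs,
               train_config = if (!is.null(model$train_config))
                 unclass(model$train_config),
               history = model$history)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a model artifact written by [save_phase_model()]
#' @param dir artifact directory.
#' @return A `phase_model`.
#' @export
load_phase_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  spec <- do.call(model_spec, meta$spec[c("input_units", "hidden_units",
                                          "final_recurrent_units",
                                          "dropout_rate",
                                          "batch_norm_momentum",
                                          "batch_norm_epsilon",
                                          "seq_len", "n_features")])
  structure(list(spec = spec,
                 params = readRDS(file.path(dir, "weights.rds")),
                 state = readRDS(file.path(dir, "bn_state.rds")),
                 history = meta$history, phase = meta$phase,
                 trained_epochs = meta$trained_epochs %||% 0L,
                 scaling = meta$scaling, seed = meta$seed),
            class = "phase_model")
}
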