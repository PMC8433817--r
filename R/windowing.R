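#' Build center-labeled sliding windows
#'
#' Cuts every contiguous length-`L` slice out of the three-channel feature
#' series and attaches, per window, the binary label of the window's center
#' frame for the requested phase (for `L = 251` the center is the 126th
#' sample, 0-based offset 125). Windows never cross recording boundaries --
#' one tensor is built per recording. Events within `(L-1)/2` frames of either
#' edge can never become positive targets, since no window centers on them.
#'
#' @param fs a `feature_set` (its three channels are min-max scaled per
#'   recording before slicing, matching the model-input convention).
#' @param labels a `labeled_series` from [make_label_channels()], or `NULL`
#'   for inference windows (targets all `NA`).
#' @param phase `"FO"`, `"MidS"` or `"FC"`.
#' @param L window length in frames, odd; default 251 (2.51 s at 100 Hz).
#' @return An object of class `window_tensor`: list with `windows`
#'   (array `N x L x 3`), `targets` (0/1 vector of length `N`),
#'   `source_frames` (0-based center frame of each window), `phase`, `L`,
#'   `center_offset`.
#' @export
make_windows <- function(fs, labels, phase = c("FO", "MidS", "FC"), L = 251) {
  phase <- match.arg(phase)
  stopifnot(inherits(fs, "feature_set"))
  if (L %% 2 == 0) stop("window length L must be odd")
  n <- fs$n_frames
  if (n < L) stop(sprintf("series too short: %d frames < window length %d", n, L))
  Fm <- feature_matrix(fs, scale = TRUE)
  N <- n - L + 1L
  C <- ncol(Fm)
  arr <- array(NA_real_, dim = c(N, L, C))
  for (t in seq_len(L)) arr[, t, ] <- Fm[t:(t + N - 1L), ]
  offset <- (L - 1L) %/% 2L
  centers <- offset + 0:(N - 1L)  # 0-based
  targets <- if (is.null(labels)) rep(NA_integer_, N)
             else label_channel(labels, phase)[centers + 1L]
  structure(list(windows = arr, targets = as.integer(targets),
                 source_frames = as.integer(centers), phase = phase,
                 L = as.integer(L), center_offset = as.integer(offset)),
            class = "window_tensor")
}

label_channel <- function(labels, phase) {
  switch(phase, FO = labels$fo, MidS = labels$mids, FC = labels$fc,
         stop("unknown phase: ", phase))
}

#' @export
print.window_tensor <- function(x, ...) {
  cat(sprintf("<window_tensor> phase=%s, %d windows of %d x %d, %d positive\n",
              x$phase, nrow(x$windows), x$L, dim(x$windows)[3],
              sum(x$targets == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Rebalance a window tensor for training
#'
#' The positive class (an event at the window center) is extremely rare in
#' the raw stream, so training on it unbalanced mostly teaches the
#' all-negative answer. Strategies: `"none"` returns the tensor unchanged
#' (the raw-stream condition); `"undersample"` keeps every positive window and
#' a seeded random subset of negatives at `ratio` negatives per positive;
#' `"target_dilation"` first widens each event's target to `1` within
#' `dilation_frames` of its center (making near-event windows positive too)
#' and then undersamples.
#'
#' @param wt a `window_tensor`.
#' @param strategy `"none"`, `"undersample"` or `"target_dilation"`.
#' @param ratio negatives kept per positive (undersampling), default 5.
#' @param dilation_frames half-width of target dilation in frames, default 2.
#' @param seed integer seed for the negative subsample.
#' @param hard_frames optional 0-based frames marking "hard" negative centers
#'   (e.g. the neighborhoods of other phases' events); when given, up to
#'   `hard_frac` of the kept negatives are drawn from windows centered on
#'   them and the remainder uniformly. Uniform negatives alone almost never
#'   include other-phase centers, and a model trained without them learns
#'   "some peak near center" instead of "this phase's peak at center".
#' @param hard_frac fraction of kept negatives drawn from `hard_frames`.
#' @return A `window_tensor` (rows sorted by source frame).
#' @export
balance_windows <- function(wt, strategy = c("none", "undersample",
                                             "target_dilation"),
                            ratio = 5, dilation_frames = 2, seed = 1,
                            hard_frames = NULL, hard_frac = 0.5) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(wt, "window_tensor"))
  if (strategy == "none") return(wt)
  targets <- wt$targets
  if (strategy == "target_dilation" && dilation_frames > 0) {
    ev <- wt$source_frames[targets == 1L]
    for (e in ev) {
      hit <- abs(wt$source_frames - e) <= dilation_frames
      targets[hit] <- 1L
    }
  }
  pos <- which(targets == 1L)
  neg <- which(targets == 0L)
  n_keep <- min(length(neg), ceiling(ratio * length(pos)))
  keep_neg <- with_seed(seed, {
    if (is.null(hard_frames)) {
      sort(sample(neg, n_keep))
    } else {
      hard <- neg[wt$source_frames[neg] %in% hard_frames]
      n_hard <- min(length(hard), round(hard_frac * n_keep))
      easy_pool <- setdiff(neg, hard)
      n_easy <- min(length(easy_pool), n_keep - n_hard)
      sort(c(sample(hard, n_hard), sample(easy_pool, n_easy)))
    }
  })
  keep <- sort(c(pos, keep_neg))
  structure(list(windows = wt$windows[keep, , , drop = FALSE],
                 targets = targets[keep],
                 source_frames = wt$source_frames[keep],
                 phase = wt$phase, L = wt$L,
                 center_offset = wt$center_offset),
            class = "window_tensor")
}

#' Concatenate window tensors from several recordings
#'
#' @param tensors list of `window_tensor` objects sharing `L` and `phase`.
#' @return A single `window_tensor`; `recording` records each window's source.
#' @export
combine_window_tensors <- function(tensors) {
  stopifnot(length(tensors) >= 1)
  L <- tensors[[1]]$L; phase <- tensors[[1]]$phase
  for (t in tensors) stopifnot(t$L == L, t$phase == phase)
  names(tensors) <- names(tensors) %||% as.character(seq_along(tensors))
  nw <- vapply(tensors, function(t) nrow(t$windows), integer(1))
  C <- dim(tensors[[1]]$windows)[3]
  arr <- array(NA_real_, dim = c(sum(nw), L, C))
  at <- 0L
  for (t in tensors) {
    k <- nrow(t$windows)
    if (k) arr[at + seq_len(k), , ] <- t$windows
    at <- at + k
  }
  structure(list(windows = arr,
                 targets = unlist(lapply(tensors, `[[`, "targets"),
                                  use.names = FALSE),
                 source_frames = unlist(lapply(tensors, `[[`, "source_frames"),
                                        use.names = FALSE),
                 recording = rep(names(tensors), nw),
                 phase = phase, L = L,
                 center_offset = tensors[[1]]$center_offset),
            class = "window_tensor")
}

#' Persist a window tensor as a directory artifact
#'
#' Writes the window array plus a JSON metadata file (window length, channel
#' count, phase, center offset and any balancing provenance) so a training
#' set can be rebuilt or audited without recomputing features.
#'
#' @param wt a `window_tensor`.
#' @param dir directory to create.
#' @param extra optional named list merged into the metadata.
#' @return `dir`, invisibly.
#' @export
write_window_tensor <- function(wt, dir, extra = list()) {
  stopifnot(inherits(wt, "window_tensor"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(wt$windows, file.path(dir, "windows.rds"))
  meta <- c(list(n_windows = nrow(wt$windows), L = wt$L,
                 n_features = dim(wt$windows)[3], phase = wt$phase,
                 center_offset = wt$center_offset,
                 targets = wt$targets, source_frames = wt$source_frames,
                 recording = wt$recording), extra)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a window tensor written by [write_window_tensor()]
#' @param dir artifact directory.
#' @return A `window_tensor`.
#' @export
read_window_tensor <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  structure(list(windows = readRDS(file.path(dir, "windows.rds")),
                 targets = as.integer(meta$targets),
                 source_frames = as.integer(meta$source_frames),
                 recording = meta$recording,
                 phase = meta$phase, L = as.integer(meta$L),
                 center_offset = as.integer(meta$center_offset)),
            class = "window_tensor")
}

#' Partition window tensors by recording
#'
#' Train/validation splitting must happen at recording granularity -- windows
#' from one recording may never appear on both sides, otherwise near-identical
#' overlapping windows leak across the split.
#'
#' @param tensors named list of `window_tensor` objects, one per recording.
#' @param val_fraction fraction of recordings held out for validation.
#' @param seed integer seed for the (recording-level) draw.
#' @return List with combined `train` and `validation` tensors and the key
#'   vectors `train_keys`, `validation_keys`.
#' @export
split_by_recording <- function(tensors, val_fraction = 0.25, seed = 1) {
  if (length(tensors) < 2L)
    stop("need at least 2 recordings to split by recording")
  keys <- names(tensors) %||% as.character(seq_along(tensors))
  names(tensors) <- keys
  n_val <- max(1L, round(val_fraction * length(keys)))
  if (n_val >= length(keys)) n_val <- length(keys) - 1L
  val_keys <- with_seed(seed, sort(sample(keys, n_val)))
  train_keys <- setdiff(keys, val_keys)
  list(train = combine_window_tensors(tensors[train_keys]),
       validation = combine_window_tensors(tensors[val_keys]),
       train_keys = train_keys, validation_keys = val_keys)
}
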