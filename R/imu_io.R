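#' Construct an IMU recording for one leg
#'
#' Bundles the seven raw channels exported per ankle sensor: tri-axial angular
#' velocity (deg/s), tri-axial free acceleration (gravity removed, m/s^2) and
#' the `Mat[1][1]` element of the orientation rotation matrix (direction cosine
#' matrix), all sampled at a common fixed rate (100 Hz by default).
#'
#' @param gyr numeric matrix with columns `Gyr_X`, `Gyr_Y`, `Gyr_Z` (deg/s).
#' @param free_acc numeric matrix with columns `FreeAcc_X`, `FreeAcc_Y`,
#'   `FreeAcc_Z` (m/s^2).
#' @param rot_mat_11 numeric vector, the `Mat[1][1]` rotation-matrix element.
#' @param side `"left"` or `"right"`.
#' @param sampling_rate_hz positive sampling rate in Hz.
#' @return An object of class `imu_recording` with fields `gyr`, `free_acc`,
#'   `rot_mat_11`, `side`, `sampling_rate_hz` and `n_frames`.
#' @export
imu_recording <- function(gyr, free_acc, rot_mat_11, side,
                          sampling_rate_hz = 100) {
  side <- match.arg(side, c("left", "right"))
  gyr <- as.matrix(gyr)
  free_acc <- as.matrix(free_acc)
  rot_mat_11 <- as.numeric(rot_mat_11)
  if (ncol(gyr) != 3L || ncol(free_acc) != 3L)
    stop("gyr and free_acc must each have 3 columns")
  n <- nrow(gyr)
  if (nrow(free_acc) != n || length(rot_mat_11) != n)
    stop("all channels must have the same number of frames")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be positive")
  colnames(gyr) <- c("Gyr_X", "Gyr_Y", "Gyr_Z")
  colnames(free_acc) <- c("FreeAcc_X", "FreeAcc_Y", "FreeAcc_Z")
  structure(
    list(side = side, sampling_rate_hz = as.numeric(sampling_rate_hz),
         gyr = gyr, free_acc = free_acc, rot_mat_11 = rot_mat_11,
         n_frames = n),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> side=%s, %d frames @ %g Hz (%.1f s)\n",
              x$side, x$n_frames, x$sampling_rate_hz,
              x$n_frames / x$sampling_rate_hz))
  invisible(x)
}

# Column-name dialects: different exporter versions write the rotation-matrix
# element as "Mat[1][1]" or "Mat_1_1". A dialect maps canonical names to the
# names present in the file.
default_column_dialect <- function() {
  list(Gyr_X = c("Gyr_X"), Gyr_Y = c("Gyr_Y"), Gyr_Z = c("Gyr_Z"),
       FreeAcc_X = c("FreeAcc_X"), FreeAcc_Y = c("FreeAcc_Y"),
       FreeAcc_Z = c("FreeAcc_Z"),
       Mat_1_1 = c("Mat[1][1]", "Mat_1_1"))
}

resolve_column <- function(canonical, candidates, available) {
  hit <- candidates[candidates %in% available]
  if (length(hit) == 0L)
    stop(sprintf("required column '%s' not found (accepted names: %s)",
                 canonical, paste(candidates, collapse = ", ")), call. = FALSE)
  hit[[1L]]
}

#' Read one leg's sensor CSV
#'
#' Reads a comma-separated motion-tracker export with a header row. Required
#' channels are the three gyroscope axes, the three free-acceleration axes and
#' the `Mat[1][1]` rotation-matrix element; extra columns are ignored and row
#' order is preserved. Column spellings can be adapted via `dialect` (by
#' default both `Mat[1][1]` and `Mat_1_1` are accepted).
#'
#' @param path path to the CSV file.
#' @param side `"left"` or `"right"`.
#' @param sampling_rate_hz sampling rate in Hz (not stored in the CSV).
#' @param dialect optional list mapping canonical channel names to accepted
#'   column names, see [default_column_dialect()].
#' @return An [imu_recording()].
#' @export
read_recording <- function(path, side, sampling_rate_hz = 100,
                           dialect = default_column_dialect()) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty input file: %s", path))
  cols <- vapply(names(dialect),
                 function(cn) resolve_column(cn, dialect[[cn]], names(df)),
                 character(1))
  imu_recording(
    gyr = as.matrix(df[, cols[c("Gyr_X", "Gyr_Y", "Gyr_Z")]]),
    free_acc = as.matrix(df[, cols[c("FreeAcc_X", "FreeAcc_Y", "FreeAcc_Z")]]),
    rot_mat_11 = df[[cols[["Mat_1_1"]]]],
    side = side, sampling_rate_hz = sampling_rate_hz)
}

#' Write one leg's sensor CSV
#'
#' Inverse of [read_recording()]: writes the seven channels with canonical
#' column names (`Mat[1][1]` for the rotation-matrix element).
#'
#' @param rec an [imu_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(rec$gyr, rec$free_acc, rec$rot_mat_11, check.names = FALSE)
  names(df) <- c("Gyr_X", "Gyr_Y", "Gyr_Z",
                 "FreeAcc_X", "FreeAcc_Y", "FreeAcc_Z", "Mat[1][1]")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pair the left and right leg recordings
#'
#' The bilateral rotation-matrix magnitude needs frame-aligned legs. If the two
#' series differ in length (wireless sensors commonly drop trailing frames)
#' both are truncated to the shorter length with a warning. Differing sampling
#' rates are an error.
#'
#' @param left,right [imu_recording()] objects for the two sides.
#' @return An object of class `paired_recording` with fields `left`, `right`.
#' @export
pair_recordings <- function(left, right) {
  stopifnot(inherits(left, "imu_recording"), inherits(right, "imu_recording"))
  if (left$sampling_rate_hz != right$sampling_rate_hz)
    stop(sprintf("sampling rates differ: %g vs %g Hz",
                 left$sampling_rate_hz, right$sampling_rate_hz))
  n <- min(left$n_frames, right$n_frames)
  if (left$n_frames != right$n_frames) {
    warning(sprintf("leg lengths differ (%d vs %d frames); truncating to %d",
                    left$n_frames, right$n_frames, n))
    left <- truncate_recording(left, n)
    right <- truncate_recording(right, n)
  }
  structure(list(left = left, right = right), class = "paired_recording")
}

truncate_recording <- function(rec, n) {
  imu_recording(rec$gyr[seq_len(n), , drop = FALSE],
                rec$free_acc[seq_len(n), , drop = FALSE],
                rec$rot_mat_11[seq_len(n)],
                rec$side, rec$sampling_rate_hz)
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf("<paired_recording> %d frames @ %g Hz\n",
              x$left$n_frames, x$left$sampling_rate_hz))
  invisible(x)
}

# ---- event tables -----------------------------------------------------------

#' Build a gait-event table
#'
#' Events are stored as a data frame with 0-based `frame` indices (frame 0 is
#' the first sample, so `time_s = frame / sampling_rate_hz`), a `phase` in
#' `FO` (foot-off), `MidS` (mid-swing) or `FC` (foot-contact), a `side` and a
#' validity flag (steps during turning or in-place movement are invalid).
#'
#' @param frame integer vector of 0-based frame indices.
#' @param phase character vector, each `"FO"`, `"MidS"` or `"FC"`.
#' @param side `"left"` or `"right"` (recycled).
#' @param valid logical vector (recycled), `TRUE` for straight-walking steps.
#' @return A `data.frame` with columns `frame`, `phase`, `side`, `valid`.
#' @export
gait_events <- function(frame = integer(), phase = character(),
                        side = character(), valid = logical()) {
  n <- length(frame)
  ev <- data.frame(frame = as.integer(frame),
                   phase = as.character(phase),
                   side = rep_len(as.character(side), n),
                   valid = rep_len(as.logical(valid), n),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(ev$phase), c("FO", "MidS", "FC"))
  if (length(bad)) stop("unknown phase: ", paste(bad, collapse = ", "))
  ev
}

#' Write a gait-event CSV
#'
#' Columns: `frame` (0-based), `time_s` (= frame / sampling rate), `side`,
#' `phase`, `valid` (0/1). Rows are written sorted by frame (stable sort).
#'
#' @param events event data frame as from [gait_events()].
#' @param path output path.
#' @param sampling_rate_hz sampling rate used to derive `time_s`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, sampling_rate_hz = 100) {
  events <- events[order(events$frame), , drop = FALSE]
  out <- data.frame(frame = as.integer(events$frame),
                    time_s = events$frame / sampling_rate_hz,
                    side = events$side,
                    phase = events$phase,
                    valid = as.integer(events$valid))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a gait-event CSV written by [write_events()]
#'
#' @param path path to the event CSV.
#' @return Event data frame with columns `frame`, `phase`, `side`, `valid`.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "side", "phase", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event table lacks columns: ", paste(miss, collapse = ", "))
  gait_events(df$frame, df$phase, df$side, df$valid == 1)
}
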