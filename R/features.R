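#' Angular-velocity magnitude
#'
#' Euclidean norm of the three gyroscope axes,
#' `sqrt(Gyr_X^2 + Gyr_Y^2 + Gyr_Z^2)` (deg/s). The magnitude is invariant
#' under any fixed rotation of the sensor axes, which is what makes it usable
#' across sensor mountings.
#'
#' @param gx,gy,gz numeric vectors, the gyroscope axis channels in deg/s.
#' @return Nonnegative numeric vector of the same length.
#' @export
ang_vel_mag <- function(gx, gy, gz) sqrt(gx^2 + gy^2 + gz^2)

#' Free-acceleration magnitude
#'
#' Euclidean norm of the three gravity-free acceleration axes (m/s^2).
#'
#' @param ax,ay,az numeric vectors, free-acceleration axis channels in m/s^2.
#' @return Nonnegative numeric vector of the same length.
#' @export
free_acc_mag <- function(ax, ay, az) sqrt(ax^2 + ay^2 + az^2)

#' Bilateral rotation-matrix magnitude
#'
#' Combines the `Mat[1][1]` direction-cosine element of both legs into
#' `sqrt(left^2 + right^2)`. During straight walking the heading, and hence
#' this magnitude, is nearly constant; it deviates while the person turns,
#' which is what the turning detector keys on. Inputs must already be cleaned
#' into `[-1, 1]` (a direction cosine cannot exceed 1), so the result is at
#' most `sqrt(2)`.
#'
#' @param left_r11,right_r11 numeric vectors in `[-1, 1]`.
#' @return Nonnegative numeric vector, bounded by `sqrt(2)`.
#' @export
rot_mat_mag <- function(left_r11, right_r11) {
  if (any(abs(left_r11) > 1) || any(abs(right_r11) > 1))
    stop("rotation-matrix elements must lie in [-1, 1]; clean the recording first")
  sqrt(left_r11^2 + right_r11^2)
}

#' Min-max scale a series to the unit interval
#'
#' `(x - min) / (max - min)`. A constant series maps to all zeros.
#'
#' @param x numeric vector.
#' @return Vector in `[0, 1]`.
#' @export
scale_unit_interval <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Compute the three smoothed magnitude features for one leg
#'
#' Builds the per-leg model input: the leg's smoothed angular-velocity
#' magnitude and free-acceleration magnitude plus the (shared) smoothed
#' bilateral rotation-matrix magnitude. Magnitudes are computed from the
#' cleaned raw channels and then Gaussian-smoothed; with
#' `cfg$smooth_raw_channels = TRUE` the raw axis channels are additionally
#' smoothed before the norms are taken (fidelity experiments only -- smoothing
#' before and after the norm are not equivalent).
#'
#' @param paired a cleaned `paired_recording` (see [clean_recording()]).
#' @param side which leg's gyroscope/acceleration to use.
#' @param cfg a [preprocess_config()].
#' @return An object of class `feature_set` with fields `side`,
#'   `ang_vel_mag`, `free_acc_mag`, `rot_mat_mag`, `ang_vel_mag_raw`
#'   (unsmoothed, kept for event refinement), `n_frames`, `sampling_rate_hz`.
#' @export
build_feature_set <- function(paired, side = c("left", "right"),
                              cfg = preprocess_config()) {
  side <- match.arg(side)
  stopifnot(inherits(paired, "paired_recording"))
  rec <- paired[[side]]
  fwhm <- cfg$smoothing_fwhm_frames
  gyr <- rec$gyr
  acc <- rec$free_acc
  l11 <- paired$left$rot_mat_11
  r11 <- paired$right$rot_mat_11
  if (cfg$smooth_raw_channels) {
    gyr <- apply(gyr, 2, smooth_gaussian, fwhm_frames = fwhm)
    acc <- apply(acc, 2, smooth_gaussian, fwhm_frames = fwhm)
    l11 <- pmin(1, pmax(-1, smooth_gaussian(l11, fwhm)))
    r11 <- pmin(1, pmax(-1, smooth_gaussian(r11, fwhm)))
  }
  avm_raw <- ang_vel_mag(gyr[, 1], gyr[, 2], gyr[, 3])
  fam_raw <- free_acc_mag(acc[, 1], acc[, 2], acc[, 3])
  rmm_raw <- rot_mat_mag(l11, r11)
  structure(
    list(side = side,
         ang_vel_mag = smooth_gaussian(avm_raw, fwhm),
         free_acc_mag = smooth_gaussian(fam_raw, fwhm),
         rot_mat_mag = smooth_gaussian(rmm_raw, fwhm),
         ang_vel_mag_raw = avm_raw,
         n_frames = rec$n_frames,
         sampling_rate_hz = rec$sampling_rate_hz),
    class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> side=%s, %d frames @ %g Hz\n",
              x$side, x$n_frames, x$sampling_rate_hz))
  invisible(x)
}

#' Feature matrix used as model input
#'
#' Returns the `n_frames x 3` matrix (AngVelMag, FreeAccMag, RotMatMag),
#' optionally min-max scaled per recording -- the scaling applied before
#' windowing and model training.
#'
#' @param fs a `feature_set`.
#' @param scale if `TRUE` (default) each channel is min-max scaled to `[0,1]`.
#' @return Numeric matrix with columns `ang_vel_mag`, `free_acc_mag`,
#'   `rot_mat_mag`.
#' @export
feature_matrix <- function(fs, scale = TRUE) {
  m <- cbind(ang_vel_mag = fs$ang_vel_mag,
             free_acc_mag = fs$free_acc_mag,
             rot_mat_mag = fs$rot_mat_mag)
  if (scale) m <- apply(m, 2, scale_unit_interval)
  m
}

#' Export a feature set as CSV
#'
#' Columns: `frame` (0-based), the three magnitude channels, `side`.
#'
#' @param fs a `feature_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fs, path) {
  df <- data.frame(frame = seq_len(fs$n_frames) - 1L,
                   ang_vel_mag = fs$ang_vel_mag,
                   free_acc_mag = fs$free_acc_mag,
                   rot_mat_mag = fs$rot_mat_mag,
                   side = fs$side)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
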