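#' Signal-cleaning configuration
#'
#' Physical validity ranges for the two sensor modalities and the width of the
#' Gaussian smoothing kernel. The ranges are the manufacturer-specified
#' measurement limits for this sensor class (+-160 m/s^2 for the
#' accelerometer, +-2000 deg/s for the gyroscope); samples outside them are
#' treated as corrupt. The kernel width is given as a full width at half
#' maximum in frames (9 frames = 90 ms at 100 Hz).
#'
#' @param acc_valid_range positive scalar, accelerometer validity bound in
#'   m/s^2 (the valid interval is symmetric, `[-b, b]`).
#' @param gyr_valid_range positive scalar, gyroscope validity bound in deg/s.
#' @param smoothing_fwhm_frames positive scalar, Gaussian FWHM in frames.
#' @param smooth_raw_channels if `TRUE`, the raw axis channels are smoothed
#'   before magnitudes are computed (in addition to the magnitude smoothing);
#'   default `FALSE`, see [build_feature_set()].
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(acc_valid_range = 160,
                              gyr_valid_range = 2000,
                              smoothing_fwhm_frames = 9,
                              smooth_raw_channels = FALSE) {
  stopifnot(acc_valid_range > 0, gyr_valid_range > 0,
            smoothing_fwhm_frames > 0)
  structure(list(acc_valid_range = acc_valid_range,
                 gyr_valid_range = gyr_valid_range,
                 smoothing_fwhm_frames = smoothing_fwhm_frames,
                 smooth_raw_channels = isTRUE(smooth_raw_channels)),
            class = "preprocess_config")
}

#' Forward-fill missing samples
#'
#' Each missing value is replaced by the nearest preceding non-missing value
#' ("pad" imputation). Leading missing values, where no preceding value
#' exists, are back-filled with the first non-missing value.
#'
#' @param x numeric vector, possibly containing `NA`.
#' @return `x` with all `NA` replaced.
#' @export
impute_pad <- function(x) {
  if (all(is.na(x))) stop("cannot impute a series with no observed values")
  if (!anyNA(x)) return(x)
  idx <- seq_along(x)
  obs <- which(!is.na(x))
  # index of the most recent observed sample at each position
  last_obs <- cummax(ifelse(is.na(x), 0L, idx))
  last_obs[last_obs == 0L] <- obs[1L]  # leading gap -> first observed value
  x[last_obs]
}

#' Remove physically impossible samples
#'
#' Samples outside the modality's valid range are treated as missing and then
#' forward-filled with [impute_pad()] (they are removed, not clipped).
#' In-range samples are untouched; the operation is idempotent.
#'
#' @param x numeric vector.
#' @param kind `"acc"` or `"gyr"`, selecting the valid range from `cfg`.
#' @param cfg a [preprocess_config()].
#' @return Cleaned numeric vector without missing values.
#' @export
remove_outliers <- function(x, kind = c("acc", "gyr"),
                            cfg = preprocess_config()) {
  kind <- match.arg(kind)
  bound <- if (kind == "acc") cfg$acc_valid_range else cfg$gyr_valid_range
  x[!is.na(x) & abs(x) > bound] <- NA_real_
  impute_pad(x)
}

#' Gaussian-smooth a signal
#'
#' Convolves the series with a discrete Gaussian kernel whose standard
#' deviation follows from the full width at half maximum,
#' sigma = FWHM / (2 * sqrt(2 * ln 2)). The kernel is truncated at 4 sigma per
#' side and normalized to sum to one, so constant signals pass through
#' unchanged; edges are handled by reflecting the series. Output length equals
#' input length.
#'
#' @param x finite numeric vector.
#' @param fwhm_frames full width at half maximum, in frames.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_gaussian <- function(x, fwhm_frames = 9) {
  if (!all(is.finite(x))) stop("smooth_gaussian requires finite input")
  stopifnot(fwhm_frames > 0)
  k <- gaussian_kernel(fwhm_frames)
  half <- (length(k) - 1L) / 2L
  n <- length(x)
  if (half == 0L) return(x)
  # reflect (without repeating the edge sample); for very short series the
  # reflection is tiled as needed
  pad_left <- rev(reflect_pad(x, half))
  pad_right <- reflect_pad(rev(x), half)
  xp <- c(pad_left, x, pad_right)
  out <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

# mirror indices 2, 3, ... (k samples beyond one edge)
reflect_pad <- function(x, k) {
  n <- length(x)
  if (n == 1L) return(rep(x, k))
  idx <- seq_len(k) + 1L
  # fold indices back into 1..n (triangular reflection for long pads)
  period <- 2L * (n - 1L)
  idx <- (idx - 1L) %% period
  idx <- ifelse(idx >= n, period - idx, idx) + 1L
  x[idx]
}

#' Discrete Gaussian kernel for a given FWHM
#'
#' @param fwhm_frames full width at half maximum in frames.
#' @return Normalized symmetric kernel (odd length, truncated at 4 sigma).
#' @export
gaussian_kernel <- function(fwhm_frames) {
  sigma <- fwhm_to_sigma(fwhm_frames)
  half <- max(1L, ceiling(4 * sigma))
  u <- (-half):half
  k <- exp(-(u^2) / (2 * sigma^2))
  k / sum(k)
}

#' Convert a full width at half maximum to a Gaussian standard deviation
#'
#' sigma = FWHM / (2 * sqrt(2 * ln 2)); for FWHM = 9 this gives ~3.822 frames.
#'
#' @param fwhm full width at half maximum.
#' @return The corresponding standard deviation.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Clean all channels of a recording
#'
#' Applies pad imputation and physical-range outlier removal to every channel
#' of one leg's recording (gyroscope range for the angular-velocity axes,
#' accelerometer range for the free-acceleration axes). The rotation-matrix
#' element is imputed and clamped into `[-1, 1]` (a direction cosine cannot
#' leave that interval; tiny numerical excursions are truncated).
#'
#' @param rec an [imu_recording()] (or `paired_recording`, cleaned per side).
#' @param cfg a [preprocess_config()].
#' @return The cleaned object of the same class.
#' @export
clean_recording <- function(rec, cfg = preprocess_config()) {
  if (inherits(rec, "paired_recording")) {
    return(structure(list(left = clean_recording(rec$left, cfg),
                          right = clean_recording(rec$right, cfg)),
                     class = "paired_recording"))
  }
  stopifnot(inherits(rec, "imu_recording"))
  gyr <- apply(rec$gyr, 2, remove_outliers, kind = "gyr", cfg = cfg)
  acc <- apply(rec$free_acc, 2, remove_outliers, kind = "acc", cfg = cfg)
  r11 <- pmin(1, pmax(-1, impute_pad(rec$rot_mat_11)))
  imu_recording(gyr, acc, r11, rec$side, rec$sampling_rate_hz)
}
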