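#' Construct a dynamic contrast-enhanced image series
#'
#' Container for one tumor's single-slice dynamic series: a
#' rows x cols x frames signal array, frame times in minutes relative to
#' injection start (baseline frames at times <= 0), injection timing
#' metadata and the tumor ROI mask.
#'
#' @param signal numeric array, `c(rows, cols, frames)`, signal >= 0.
#' @param frame_times strictly increasing, minutes; the first
#'   `n_baseline_frames` entries must be <= 0.
#' @param n_baseline_frames number of pre-contrast frames (>= 1).
#' @param nominal_injection_duration seconds.
#' @param actual_injection_duration seconds.
#' @param roi_mask logical rows x cols matrix.
#' @return a `dce_series` object.
#' @export
dce_series <- function(signal, frame_times, n_baseline_frames,
                       nominal_injection_duration = 3,
                       actual_injection_duration = nominal_injection_duration,
                       roi_mask = NULL) {
  if (length(dim(signal)) != 3L) stopf("dce_series: signal must be a 3-D array")
  nf <- dim(signal)[3]
  if (length(frame_times) != nf) {
    stopf("dce_series: %d frame times for %d frames", length(frame_times), nf)
  }
  if (any(diff(frame_times) <= 0)) {
    stopf("dce_series: frame_times must be strictly increasing")
  }
  nb <- as.integer(n_baseline_frames)
  if (nb < 1L || nb >= nf) stopf("dce_series: need 1 <= n_baseline_frames < n_frames")
  if (any(frame_times[seq_len(nb)] > 0)) {
    stopf("dce_series: baseline frames must have frame_times <= 0")
  }
  if (any(signal < 0)) stopf("dce_series: signal must be >= 0")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, dim(signal)[1], dim(signal)[2])
  if (!all(dim(roi_mask) == dim(signal)[1:2])) {
    stopf("dce_series: roi_mask dimensions must match the image grid")
  }
  structure(list(signal = signal, frame_times = as.numeric(frame_times),
                 n_baseline_frames = nb,
                 nominal_injection_duration = nominal_injection_duration,
                 actual_injection_duration = actual_injection_duration,
                 roi_mask = roi_mask),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dce_series> %dx%d voxels, %d frames (%d baseline), %d ROI voxels\n",
              d[1], d[2], d[3], x$n_baseline_frames, sum(x$roi_mask)))
  cat(sprintf("  times %.2f .. %.2f min; injection %.1f s (nominal %.1f s)\n",
              min(x$frame_times), max(x$frame_times),
              x$actual_injection_duration, x$nominal_injection_duration))
  invisible(x)
}

#' Align the post-contrast time axis on the bolus midpoint
#'
#' When the realized injection duration deviates from the nominal one,
#' the recorded post-contrast frame times are displaced relative to the
#' effective bolus midpoint. The correction shifts every post-contrast
#' frame time by `(actual - nominal) / 2` (converted to minutes), so
#' curves from different tumors share a common effective time origin;
#' baseline frames are left untouched.
#'
#' @param series a [dce_series].
#' @return the series with corrected `frame_times` (and the actual
#'   duration reset to nominal, marking the correction as applied).
#' @export
correct_time_axis <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  if (series$actual_injection_duration <= 0) {
    stopf("correct_time_axis: actual_injection_duration must be > 0")
  }
  shift <- (series$actual_injection_duration -
              series$nominal_injection_duration) / 2 / 60
  if (shift != 0) {
    post <- seq.int(series$n_baseline_frames + 1L, length(series$frame_times))
    series$frame_times[post] <- series$frame_times[post] + shift
    series$actual_injection_duration <- series$nominal_injection_duration
  }
  series
}

#' Relative signal intensity curves for every voxel
#'
#' Converts the raw dynamic signal to relative enhancement,
#' \eqn{RSI(t) = (SI(t) - SI(0)) / SI(0)}, where \eqn{SI(0)} is the mean
#' over all pre-contrast baseline frames of the voxel. Only
#' post-contrast frames are retained. Voxels whose baseline mean is not
#' strictly positive cannot be normalized and are flagged non-evaluable
#' rather than raising an error; they are excluded downstream.
#'
#' @param series a [dce_series].
#' @return an `rsi_stack`: `rsi` array (rows x cols x post-frames),
#'   post-contrast `times` (minutes), and logical `evaluable` matrix.
#' @export
compute_rsi <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  nb <- series$n_baseline_frames
  nf <- dim(series$signal)[3]
  base_idx <- seq_len(nb)
  post_idx <- seq.int(nb + 1L, nf)
  si0 <- apply(series$signal[, , base_idx, drop = FALSE], c(1, 2), mean)
  evaluable <- si0 > 0
  rsi <- series$signal[, , post_idx, drop = FALSE]
  denom <- ifelse(evaluable, si0, NA_real_)
  rsi <- sweep(sweep(rsi, c(1, 2), denom, "-"), c(1, 2), denom, "/")
  structure(list(rsi = rsi, times = series$frame_times[post_idx],
                 evaluable = evaluable, baseline = si0),
            class = "rsi_stack")
}

# Single-voxel enhancement curve.
rsi_curve <- function(times, rsi) {
  if (length(times) != length(rsi)) stopf("rsi_curve: length mismatch")
  if (any(times <= 0)) stopf("rsi_curve: post-contrast times must be > 0")
  structure(list(times = as.numeric(times), rsi = as.numeric(rsi)),
            class = "rsi_curve")
}
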