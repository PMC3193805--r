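#' Write a DCE series to NIfTI with a JSON timing sidecar
#'
#' The 4D series is stored as x, y, z = 1, t; the ROI mask as a 0/1
#' integer volume on the same grid; frame times, baseline-frame count
#' and injection durations go to a JSON sidecar.
#'
#' @param series a [dce_series].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of file paths written.
#' @export
write_dce_nifti <- function(series, dir, prefix = "dce") {
  stopifnot(inherits(series, "dce_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$signal)
  arr4 <- array(series$signal, dim = c(d[1], d[2], 1L, d[3]))
  paths <- c(
    series = file.path(dir, paste0(prefix, "_series.nii.gz")),
    mask = file.path(dir, paste0(prefix, "_mask.nii.gz")),
    timing = file.path(dir, paste0(prefix, "_timing.json")))
  RNifti::writeNifti(RNifti::asNifti(arr4), paths[["series"]])
  mask4 <- array(as.integer(series$roi_mask), dim = c(d[1], d[2], 1L))
  RNifti::writeNifti(RNifti::asNifti(mask4, datatype = "int16"),
                     paths[["mask"]])
  jsonlite::write_json(list(
    frame_times_min = series$frame_times,
    n_baseline_frames = series$n_baseline_frames,
    nominal_injection_duration_s = series$nominal_injection_duration,
    actual_injection_duration_s = series$actual_injection_duration),
    paths[["timing"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a DCE series written by [write_dce_nifti()]
#'
#' @param series_path 4D NIfTI series (x, y, 1, t).
#' @param mask_path ROI mask NIfTI on the same grid.
#' @param timing_path JSON timing sidecar.
#' @return a [dce_series].
#' @export
read_dce_nifti <- function(series_path, mask_path, timing_path) {
  for (p in c(series_path, mask_path, timing_path)) {
    if (!file.exists(p)) stopf("read_dce_nifti: file not found: %s", p)
  }
  arr <- as.array(RNifti::readNifti(series_path))
  if (length(dim(arr)) == 4L) {
    arr <- array(arr, dim = c(dim(arr)[1], dim(arr)[2], dim(arr)[4]))
  }
  mask <- as.array(RNifti::readNifti(mask_path))
  mask <- matrix(as.logical(mask), dim(mask)[1], dim(mask)[2])
  tm <- jsonlite::read_json(timing_path, simplifyVector = TRUE)
  dce_series(signal = arr, frame_times = tm$frame_times_min,
             n_baseline_frames = tm$n_baseline_frames,
             nominal_injection_duration = tm$nominal_injection_duration_s,
             actual_injection_duration = tm$actual_injection_duration_s,
             roi_mask = mask)
}

#' Write ground-truth parameter maps as NIfTI volumes
#' @param truth a `ground_truth` object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_truth_nifti <- function(truth, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("A", "kep", "kel")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(RNifti::asNifti(
      array(truth[[nm]], dim = c(dim(truth[[nm]]), 1L))), p)
    paths[nm] <- p
  }
  paths["roi"] <- file.path(dir, paste0(prefix, "_roi.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(
    array(as.integer(truth$roi), dim = c(dim(truth$roi), 1L)),
    datatype = "int16"), paths[["roi"]])
  invisible(paths)
}

#' Read / write caliper measurement tables
#'
#' Plain CSV with columns `tumor_id`, `group`, `day`, `length_mm`,
#' `width_mm`.
#'
#' @param caliper caliper data.frame.
#' @param path CSV file path.
#' @return `read_caliper_csv` returns the validated data.frame.
#' @export
write_caliper_csv <- function(caliper, path) {
  utils::write.csv(caliper, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_caliper_csv
#' @export
read_caliper_csv <- function(path) {
  if (!file.exists(path)) stopf("read_caliper_csv: file not found: %s", path)
  caliper <- utils::read.csv(path, stringsAsFactors = FALSE)
  add_volumes(caliper)[, c("tumor_id", "group", "day", "length_mm",
                           "width_mm")]
}

#' Export per-voxel fits as CSV
#' @param map a `parametric_map` from [fit_roi()].
#' @param path CSV file path.
#' @export
write_parametric_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
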